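#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of a position-specific scoring matrix to
// a protein segment with affine gaps. A gap of length g costs open + g*ext.
// States: M (profile column i aligned to residue j), D (column i deleted:
// gap in the target), I (residue j inserted: gap in the profile). M may
// follow any state (or start fresh), D follows M or D, I follows M or I
// (adjacent D/I pairs are never optimal here because a single M move is
// always cheaper than two gap openings). Alignments start and end in M;
// coverage counts all profile columns between p_start and p_end, i.e.
// matches and deletions.
//
// S: L x 20 matrix of column scores (half-bits).
// target: 0-based residue indices into the scoring alphabet; -1 = unknown
// (scored unknown_score).
// Returns 1-based inclusive coordinates (p_start, p_end, t_start, t_end);
// score 0 with zeroed coordinates means no positive-scoring alignment. Ties
// resolve to the smallest (column, residue) end cell.
// [[Rcpp::export]]
List profile_sw_cpp(NumericMatrix S, IntegerVector target, double gap_open,
                    double gap_ext, double unknown_score = -4.0) {
  const int L = S.nrow();
  const int n = target.size();
  const double NEG = -1e30;
  const double open_cost = gap_open + gap_ext;

  // previous row (profile column i-1) and current row; start coordinates of
  // the local alignment are carried along with each state's score.
  std::vector<double> Mp(n + 1, NEG), Mc(n + 1, NEG);
  std::vector<double> Dp(n + 1, NEG), Dc(n + 1, NEG);
  std::vector<double> Ip(n + 1, NEG), Ic(n + 1, NEG);
  std::vector<int> MpP(n + 1), McP(n + 1), MpT(n + 1), McT(n + 1);
  std::vector<int> DpP(n + 1), DcP(n + 1), DpT(n + 1), DcT(n + 1);
  std::vector<int> IpP(n + 1), IcP(n + 1), IpT(n + 1), IcT(n + 1);

  double best = 0.0;
  int bp1 = 0, bp2 = 0, bt1 = 0, bt2 = 0;

  for (int i = 1; i <= L; ++i) {
    Mc[0] = NEG;
    Dc[0] = NEG;
    Ic[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      int aa = target[j - 1];
      double sub = (aa >= 0) ? S(i - 1, aa) : unknown_score;

      // M(i,j): best of fresh start and the three states at (i-1, j-1)
      double prev = 0.0;
      int sp = i, st = j;
      if (Mp[j - 1] > prev) { prev = Mp[j - 1]; sp = MpP[j - 1]; st = MpT[j - 1]; }
      if (Dp[j - 1] > prev) { prev = Dp[j - 1]; sp = DpP[j - 1]; st = DpT[j - 1]; }
      if (Ip[j - 1] > prev) { prev = Ip[j - 1]; sp = IpP[j - 1]; st = IpT[j - 1]; }
      Mc[j] = prev + sub;
      McP[j] = sp;
      McT[j] = st;

      // D(i,j): profile column i deleted; predecessor at (i-1, j)
      double dM = Mp[j] - open_cost;
      double dD = Dp[j] - gap_ext;
      if (dM >= dD) { Dc[j] = dM; DcP[j] = MpP[j]; DcT[j] = MpT[j]; }
      else { Dc[j] = dD; DcP[j] = DpP[j]; DcT[j] = DpT[j]; }

      // I(i,j): residue j inserted; predecessor at (i, j-1), already final
      double iM = Mc[j - 1] - open_cost;
      double iI = Ic[j - 1] - gap_ext;
      if (iM >= iI) { Ic[j] = iM; IcP[j] = McP[j - 1]; IcT[j] = McT[j - 1]; }
      else { Ic[j] = iI; IcP[j] = IcP[j - 1]; IcT[j] = IcT[j - 1]; }

      if (Mc[j] > best) {
        best = Mc[j];
        bp1 = McP[j];
        bt1 = McT[j];
        bp2 = i;
        bt2 = j;
      }
    }
    std::swap(Mp, Mc); std::swap(MpP, McP); std::swap(MpT, McT);
    std::swap(Dp, Dc); std::swap(DpP, DcP); std::swap(DpT, DcT);
    std::swap(Ip, Ic); std::swap(IpP, IcP); std::swap(IpT, IcT);
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Dc.begin(), Dc.end(), NEG);
    std::fill(Ic.begin(), Ic.end(), NEG);
  }

  return List::create(_["score"] = best, _["p_start"] = bp1,
                      _["p_end"] = bp2, _["t_start"] = bt1,
                      _["t_end"] = bt2);
}
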