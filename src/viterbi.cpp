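#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Glocal (model-global, sequence-local) Viterbi in log2-odds space.
// Flanking sequence outside the aligned core is emitted at background
// frequency with no transition cost, so its log-odds contribution is
// exactly zero and bit scores are invariant under appended background
// flanks.
//
// seq: integer vector, 1..4 = A,C,G,T; 0 = N (scores 0 bits everywhere)
// mE, iE: L x 4 matrices of log2(e / background)
// tM: L x 3 (out of M_k: MM MI MD); tI: L x 2 (IM II); tD: L x 2 (DM DD)
// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(IntegerVector seq, NumericMatrix mE, NumericMatrix iE,
                 NumericVector tBM_, NumericVector tBD_,
                 NumericMatrix tM, NumericMatrix tI, NumericMatrix tD) {
  const int L = mE.nrow();
  const int n = seq.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double tBM = tBM_[0], tBD = tBD_[0];
  const int W = n + 1;

  // flat copies for fast access: emissions by [state][base]
  std::vector<double> me(L * 5), ie(L * 5);
  for (int k = 0; k < L; ++k) {
    me[k * 5] = 0.0; ie[k * 5] = 0.0;  // N
    for (int b = 0; b < 4; ++b) {
      me[k * 5 + 1 + b] = mE(k, b);
      ie[k * 5 + 1 + b] = iE(k, b);
    }
  }
  std::vector<double> tmm(L), tmi(L), tmd(L), tim(L), tii(L), tdm(L),
      tdd(L);
  for (int k = 0; k < L; ++k) {
    tmm[k] = tM(k, 0); tmi[k] = tM(k, 1); tmd[k] = tM(k, 2);
    tim[k] = tI(k, 0); tii[k] = tI(k, 1);
    tdm[k] = tD(k, 0); tdd[k] = tD(k, 1);
  }
  std::vector<int> sq(n);
  for (int i = 0; i < n; ++i) sq[i] = seq[i];

  // DP rows over boundaries i = 0..n; rows indexed by state k = 1..L
  std::vector<double> VM((L + 1) * W, NEG), VI((L + 1) * W, NEG),
      VD((L + 1) * W, NEG);
  std::vector<signed char> PM((L + 1) * W, 0), PI((L + 1) * W, 0),
      PD((L + 1) * W, 0);
  // traceback codes: 1 from M, 2 from I, 3 from D, 4 from B

  for (int k = 1; k <= L; ++k) {
    double *vmk = &VM[k * W], *vik = &VI[k * W], *vdk = &VD[k * W];
    const double *vmp = &VM[(k - 1) * W], *vip = &VI[(k - 1) * W],
        *vdp = &VD[(k - 1) * W];
    signed char *pmk = &PM[k * W], *pik = &PI[k * W], *pdk = &PD[k * W];
    const double *mek = &me[(k - 1) * 5], *iek = &ie[(k - 1) * 5];
    const double cMM = (k >= 2) ? tmm[k - 2] : 0.0;
    const double cIM = (k >= 2) ? tim[k - 2] : 0.0;
    const double cDM = (k >= 2) ? tdm[k - 2] : 0.0;
    const double cDD = (k >= 2) ? tdd[k - 2] : 0.0;
    const double cMD = (k >= 2) ? tmd[k - 2] : 0.0;
    const double cMI = tmi[k - 1], cII = tii[k - 1];
    const bool hasIns = (k < L);
    for (int i = 0; i <= n; ++i) {
      // delete state at boundary i (consumes nothing)
      double bestD; signed char pd;
      if (k == 1) { bestD = tBD; pd = 4; }
      else {
        double fm = vmp[i] + cMD;
        double fd = vdp[i] + cDD;
        if (fm >= fd) { bestD = fm; pd = 1; } else { bestD = fd; pd = 3; }
      }
      vdk[i] = bestD; pdk[i] = pd;

      if (i >= 1) {
        const double em = mek[sq[i - 1]];
        double bestM; signed char pm;
        if (k == 1) { bestM = tBM; pm = 4; }
        else {
          double fm = vmp[i - 1] + cMM;
          double fi = vip[i - 1] + cIM;
          double fd = vdp[i - 1] + cDM;
          bestM = fm; pm = 1;
          if (fi > bestM) { bestM = fi; pm = 2; }
          if (fd > bestM) { bestM = fd; pm = 3; }
        }
        vmk[i] = bestM + em; pmk[i] = pm;

        if (hasIns) {
          double fm = vmk[i - 1] + cMI;
          double fi = vik[i - 1] + cII;
          double bestI; signed char pi_;
          if (fm >= fi) { bestI = fm; pi_ = 1; } else { bestI = fi; pi_ = 2; }
          vik[i] = bestI + iek[sq[i - 1]]; pik[i] = pi_;
        }
      }
    }
  }

  // end: exit from M_L or D_L at any boundary; trailing flank is free
  double best = NEG; int bestI = 0; int bestKind = 1;
  const double *vmL = &VM[L * W], *vdL = &VD[L * W];
  for (int i = 0; i <= n; ++i) {
    if (vmL[i] > best) { best = vmL[i]; bestI = i; bestKind = 1; }
    if (vdL[i] > best) { best = vdL[i]; bestI = i; bestKind = 3; }
  }

  // traceback
  std::vector<int> kinds, models, seqpos;
  int k = L, i = bestI, kind = bestKind;
  while (true) {
    signed char p;
    if (kind == 1) {
      kinds.push_back(1); models.push_back(k); seqpos.push_back(i);
      p = PM[k * W + i]; --i;
      if (p == 4) break;
      kind = p; --k;
    } else if (kind == 2) {
      kinds.push_back(2); models.push_back(k); seqpos.push_back(i);
      p = PI[k * W + i]; --i;
      kind = p;
    } else {
      kinds.push_back(3); models.push_back(k); seqpos.push_back(NA_INTEGER);
      p = PD[k * W + i];
      if (p == 4) break;
      kind = p; --k;
    }
  }
  std::reverse(kinds.begin(), kinds.end());
  std::reverse(models.begin(), models.end());
  std::reverse(seqpos.begin(), seqpos.end());

  return List::create(_["score"] = best, _["kind"] = wrap(kinds),
                      _["model"] = wrap(models), _["seqpos"] = wrap(seqpos));
}
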