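#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Local multihit profile-HMM scoring.
//
// Architecture (generative):
//   N --(eta, emit bg)--> N ; N --(1-eta)--> B
//   B --(1/L)--> M_j                     (uniform local entry)
//   M_j --(eps)--> E (j<L); M_L --> E with prob 1
//   M_j --((1-eps) tMM)--> M_{j+1}; --((1-eps) tMI)--> I_j;
//       --((1-eps) tMD)--> D_{j+1}
//   I_j --(tIM)--> M_{j+1}; --(tII)--> I_j          (j = 1..L-1)
//   D_j --(tDM)--> M_{j+1}; --(tDD)--> D_{j+1}; D_L --> E
//   E --(0.5)--> J; E --(0.5)--> C                  (multihit)
//   J --(eta, emit bg)--> J; J --(1-eta)--> B
//   C --(eta, emit bg)--> C; C --(1-eta)--> end
// Null model: emits each residue with prob eta * bg, terminates with 1-eta.
// Flank emissions therefore cancel exactly against the null.
//
// obs: 0-based symbol indices; -1 marks an ambiguous residue, which emits
// probability 1 in every state including the null (odds contribution 1).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct HmmPar {
  int L, K, n;
  const double *lmat, *lins;         // L x K, (L+1) x K log emissions
  const double *lMM, *lMI, *lMD, *lIM, *lII, *lDM, *lDD; // length L
  std::vector<double> lbg;           // log background
  double leps, l1meps, leta, l1meta, lentry, lhalf;
  const int *obs;
  // emission log-prob of symbol s in match state j (1-based)
  double em(int j, int s) const {
    return s < 0 ? 0.0 : lmat[(j - 1) + (size_t)s * L];
  }
  double ei(int j, int s) const {  // insert state I_j uses row j+1 (1-based)
    return s < 0 ? 0.0 : lins[j + (size_t)s * (L + 1)];
  }
  double ebg(int s) const { return s < 0 ? 0.0 : lbg[s]; }
  double lexit(int j) const { return j == L ? 0.0 : leps; }
  double lcore(int j) const { return j == L ? NEG_INF : l1meps; }
};

static HmmPar make_par(const IntegerVector &obs, const NumericMatrix &lmat,
                       const NumericMatrix &lins, const NumericMatrix &ltr,
                       const NumericVector &lbg, double eps, double eta) {
  HmmPar p;
  p.L = lmat.nrow();
  p.K = lmat.ncol();
  p.n = obs.size();
  p.lmat = REAL(lmat); p.lins = REAL(lins);
  p.lMM = &ltr(0, 0); p.lMI = &ltr(0, 1); p.lMD = &ltr(0, 2);
  p.lIM = &ltr(0, 3); p.lII = &ltr(0, 4);
  p.lDM = &ltr(0, 5); p.lDD = &ltr(0, 6);
  p.lbg.assign(lbg.begin(), lbg.end());
  p.leps = std::log(eps);
  p.l1meps = std::log1p(-eps);
  p.leta = std::log(eta);
  p.l1meta = std::log1p(-eta);
  p.lentry = -std::log((double)p.L);
  p.lhalf = std::log(0.5);
  p.obs = INTEGER(obs);
  return p;
}

// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(IntegerVector obs, NumericMatrix lmat,
                       NumericMatrix lins, NumericMatrix ltr,
                       NumericVector lbg, double eps, double eta) {
  HmmPar p = make_par(obs, lmat, lins, ltr, lbg, eps, eta);
  const int L = p.L, n = p.n;
  std::vector<double> Mc((L + 1) * (n + 1), NEG_INF), Ic((L + 1) * (n + 1), NEG_INF),
      Dc((L + 1) * (n + 1), NEG_INF);
  std::vector<double> Nv(n + 1, NEG_INF), Bv(n + 1, NEG_INF), Ev(n + 1, NEG_INF),
      Jv(n + 1, NEG_INF), Cv(n + 1, NEG_INF);
  auto M = [&](int j, int i) -> double & { return Mc[j * (n + 1) + i]; };
  auto I = [&](int j, int i) -> double & { return Ic[j * (n + 1) + i]; };
  auto D = [&](int j, int i) -> double & { return Dc[j * (n + 1) + i]; };

  Nv[0] = 0.0;
  Bv[0] = Nv[0] + p.l1meta;
  for (int i = 1; i <= n; ++i) {
    int s = p.obs[i - 1];
    double bg = p.leta + p.ebg(s);
    for (int j = 1; j <= L; ++j) {
      double acc = Bv[i - 1] + p.lentry;
      if (j > 1) {
        acc = lse(acc, M(j - 1, i - 1) + p.lcore(j - 1) + p.lMM[j - 2]);
        acc = lse(acc, I(j - 1, i - 1) + p.lIM[j - 2]);
        acc = lse(acc, D(j - 1, i - 1) + p.lDM[j - 2]);
      }
      M(j, i) = acc + p.em(j, s);
      if (j < L) {
        double ai = lse(M(j, i - 1) + p.lcore(j) + p.lMI[j - 1],
                        I(j, i - 1) + p.lII[j - 1]);
        I(j, i) = ai + p.ei(j, s);
      }
      if (j > 1) {
        D(j, i) = lse(M(j - 1, i) + p.lcore(j - 1) + p.lMD[j - 2],
                      D(j - 1, i) + p.lDD[j - 2]);
      }
    }
    double e = NEG_INF;
    for (int j = 1; j <= L; ++j) e = lse(e, M(j, i) + p.lexit(j));
    e = lse(e, D(L, i));  // D_L -> E with prob 1
    Ev[i] = e;
    Nv[i] = Nv[i - 1] + bg;
    Jv[i] = lse(Ev[i] + p.lhalf, (i >= 1 ? Jv[i - 1] : NEG_INF) + bg);
    Cv[i] = lse(Ev[i] + p.lhalf, (i >= 1 ? Cv[i - 1] : NEG_INF) + bg);
    Bv[i] = lse(Nv[i] + p.l1meta, Jv[i] + p.l1meta);
  }
  if (n == 0) return NA_REAL;
  double logPmodel = Cv[n] + p.l1meta;
  double logPnull = p.l1meta;
  for (int i = 0; i < n; ++i) logPnull += p.leta + p.ebg(p.obs[i]);
  return (logPmodel - logPnull) / std::log(2.0);
}

// Viterbi with traceback. Returns bits and the state path as parallel
// vectors: state code (0=N,1=B,2=M,3=I,4=D,5=E,6=J,7=C), node index (0 for
// non-core states) and emitted sequence position (0 if silent step).
// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
List hmm_viterbi_cpp(IntegerVector obs, NumericMatrix lmat,
                     NumericMatrix lins, NumericMatrix ltr,
                     NumericVector lbg, double eps, double eta) {
  HmmPar p = make_par(obs, lmat, lins, ltr, lbg, eps, eta);
  const int L = p.L, n = p.n;
  // back-pointer codes: predecessor state at known (j,i)
  std::vector<double> Mc((L + 1) * (n + 1), NEG_INF), Ic((L + 1) * (n + 1), NEG_INF),
      Dc((L + 1) * (n + 1), NEG_INF);
  std::vector<int> bM((L + 1) * (n + 1), -1), bI((L + 1) * (n + 1), -1),
      bD((L + 1) * (n + 1), -1), bE(n + 1, -1), bJ(n + 1, -1), bC(n + 1, -1),
      bB(n + 1, -1);
  std::vector<double> Nv(n + 1, NEG_INF), Bv(n + 1, NEG_INF), Ev(n + 1, NEG_INF),
      Jv(n + 1, NEG_INF), Cv(n + 1, NEG_INF);
  auto idx = [&](int j, int i) { return j * (n + 1) + i; };

  Nv[0] = 0.0;
  Bv[0] = Nv[0] + p.l1meta; bB[0] = 0;  // from N
  for (int i = 1; i <= n; ++i) {
    int s = p.obs[i - 1];
    double bg = p.leta + p.ebg(s);
    for (int j = 1; j <= L; ++j) {
      double best = Bv[i - 1] + p.lentry; int who = 1; // from B
      if (j > 1) {
        double v = Mc[idx(j - 1, i - 1)] + p.lcore(j - 1) + p.lMM[j - 2];
        if (v > best) { best = v; who = 2; }
        v = Ic[idx(j - 1, i - 1)] + p.lIM[j - 2];
        if (v > best) { best = v; who = 3; }
        v = Dc[idx(j - 1, i - 1)] + p.lDM[j - 2];
        if (v > best) { best = v; who = 4; }
      }
      Mc[idx(j, i)] = best + p.em(j, s); bM[idx(j, i)] = who;
      if (j < L) {
        double a = Mc[idx(j, i - 1)] + p.lcore(j) + p.lMI[j - 1]; int w = 2;
        double v = Ic[idx(j, i - 1)] + p.lII[j - 1];
        if (v > a) { a = v; w = 3; }
        Ic[idx(j, i)] = a + p.ei(j, s); bI[idx(j, i)] = w;
      }
      if (j > 1) {
        double a = Mc[idx(j - 1, i)] + p.lcore(j - 1) + p.lMD[j - 2]; int w = 2;
        double v = Dc[idx(j - 1, i)] + p.lDD[j - 2];
        if (v > a) { a = v; w = 4; }
        Dc[idx(j, i)] = a; bD[idx(j, i)] = w;
      }
    }
    double e = NEG_INF; int ewho = -1;
    for (int j = 1; j <= L; ++j) {
      double v = Mc[idx(j, i)] + p.lexit(j);
      if (v > e) { e = v; ewho = j; }
    }
    if (Dc[idx(L, i)] > e) { e = Dc[idx(L, i)]; ewho = -L; } // from D_L
    Ev[i] = e; bE[i] = ewho;
    Nv[i] = Nv[i - 1] + bg;
    { double a = Ev[i] + p.lhalf; int w = 5;
      double v = Jv[i - 1] + bg;
      if (v > a) { a = v; w = 6; }
      Jv[i] = a; bJ[i] = w; }
    { double a = Ev[i] + p.lhalf; int w = 5;
      double v = Cv[i - 1] + bg;
      if (v > a) { a = v; w = 7; }
      Cv[i] = a; bC[i] = w; }
    { double a = Nv[i] + p.l1meta; int w = 0;
      double v = Jv[i] + p.l1meta;
      if (v > a) { a = v; w = 6; }
      Bv[i] = a; bB[i] = w; }
  }
  double logPmodel = Cv[n] + p.l1meta;
  double logPnull = p.l1meta;
  for (int i = 0; i < n; ++i) logPnull += p.leta + p.ebg(p.obs[i]);
  double bits = (logPmodel - logPnull) / std::log(2.0);

  // traceback from C at position n
  std::vector<int> st, nd, ps;
  int state = 7, j = 0, i = n;
  while (!(state == 0 && i == 0)) {
    st.push_back(state); nd.push_back(j); ps.push_back(0);
    switch (state) {
    case 7: { // C emitted x_i if predecessor C, else silent from E
      int w = bC[i];
      if (w == 7) { ps.back() = i; --i; }
      state = w; break; }
    case 6: {
      int w = bJ[i];
      if (w == 6) { ps.back() = i; --i; }
      state = w; break; }
    case 5: {
      int w = bE[i];
      if (w > 0) { state = 2; j = w; }
      else { state = 4; j = -w; }
      break; }
    case 2: { // M_j emitted x_i
      ps.back() = i;
      int w = bM[idx(j, i)];
      --i;
      if (w == 1) { state = 1; j = 0; }
      else { state = w; --j; }
      break; }
    case 3: { // I_j emitted x_i
      ps.back() = i;
      int w = bI[idx(j, i)];
      --i;
      state = w; // same node
      break; }
    case 4: {
      int w = bD[idx(j, i)];
      state = w; --j;
      break; }
    case 1: {
      state = bB[i]; j = 0;
      break; }
    case 0: { // N flank: emits while residues remain
      if (i > 0) { ps.back() = i; --i; }
      break; }
    default: stop("traceback error");
    }
  }
  st.push_back(0); nd.push_back(0); ps.push_back(0); // initial N
  std::reverse(st.begin(), st.end());
  std::reverse(nd.begin(), nd.end());
  std::reverse(ps.begin(), ps.end());
  return List::create(_["bits"] = bits, _["state"] = wrap(st),
                      _["node"] = wrap(nd), _["pos"] = wrap(ps));
}
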