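#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Frameshift-aware global alignment of a nucleotide query against a
// protein reference. Each reference residue may consume 1..5 query
// nucleotides; consumptions other than 3 are frameshifts penalised by
// fs_pen per unit of shift (|c - 3|). Damaged codons (c != 3) are scored
// and emitted by reference-guided repair: the best completion (c < 3) or
// base deletion (c > 3) of the codon under the substitution matrix.
// Affine gaps: a gap of length k costs gap_open + k * gap_ext. Query-side
// gaps are codon-sized (3 nt, translated and emitted), reference-side
// gaps consume one reference residue.
//
// qry: 0-based nucleotide indices (0..3), -1 ambiguous.
// ref: 0-based indices into the substitution alphabet.
// codon_aa: length-64 map codon -> alphabet index (16*b1 + 4*b2 + b3).
// xa: alphabet index of 'X' (used for ambiguous codons).
// sub: square substitution matrix over the alphabet.

static const double NEG = -1e18;

struct Sub {
  const double *s; int K;
  double operator()(int a, int b) const { return s[a + (size_t)b * K]; }
};

static inline int codon_index(int a, int b, int c) {
  if (a < 0 || b < 0 || c < 0) return -1;
  return 16 * a + 4 * b + c;
}

// best repair score and emitted aa for a consumption of length c ending at
// query position i (1-based), against reference residue r.
static void repair(const int *q, int i, int c, int r, const int *codon_aa,
                   int xa, const Sub &S, double &sc, int &aa) {
  sc = NEG; aa = xa;
  int b[5];
  for (int k = 0; k < c; ++k) b[k] = q[i - c + k];
  if (c == 3) {
    int ci = codon_index(b[0], b[1], b[2]);
    aa = ci < 0 ? xa : codon_aa[ci];
    sc = S(aa, r);
  } else if (c == 4) {           // drop one of four bases (+1 shift)
    for (int drop = 0; drop < 4; ++drop) {
      int t[3], m = 0;
      for (int k = 0; k < 4; ++k) if (k != drop) t[m++] = b[k];
      int ci = codon_index(t[0], t[1], t[2]);
      int a = ci < 0 ? xa : codon_aa[ci];
      if (S(a, r) > sc) { sc = S(a, r); aa = a; }
    }
  } else if (c == 2) {           // insert one base at one of 3 positions
    for (int pos = 0; pos < 3; ++pos)
      for (int base = 0; base < 4; ++base) {
        int t[3], m = 0;
        for (int k = 0; k < 3; ++k) t[k] = -2;
        t[pos] = base;
        for (int k = 0; k < 3; ++k) if (t[k] == -2) t[k] = b[m++];
        int ci = codon_index(t[0], t[1], t[2]);
        int a = ci < 0 ? xa : codon_aa[ci];
        if (S(a, r) > sc) { sc = S(a, r); aa = a; }
      }
  } else if (c == 5) {           // keep 3 of 5 in order (+2 shift)
    for (int d1 = 0; d1 < 4; ++d1)
      for (int d2 = d1 + 1; d2 < 5; ++d2) {
        int t[3], m = 0;
        for (int k = 0; k < 5; ++k) if (k != d1 && k != d2) t[m++] = b[k];
        int ci = codon_index(t[0], t[1], t[2]);
        int a = ci < 0 ? xa : codon_aa[ci];
        if (S(a, r) > sc) { sc = S(a, r); aa = a; }
      }
  } else if (c == 1) {           // two bases lost (-2 shift): best = ref
    sc = S(r, r); aa = r;
  }
}

// [[Rcpp::export(name = ".framebot_cpp")]]
List framebot_cpp(IntegerVector qry, IntegerVector ref, IntegerVector codon_aa,
                  int xa, NumericMatrix sub, double fs_pen, double gap_open,
                  double gap_ext, int max_shift) {
  const int n = qry.size(), m = ref.size();
  Sub S{REAL(sub), sub.nrow()};
  const int *q = INTEGER(qry);
  const int *r = INTEGER(ref);
  const int *caa = INTEGER(codon_aa);
  const int cmin = 3 - max_shift < 1 ? 1 : 3 - max_shift;
  const int cmax = 3 + max_shift;

  // DP over (i, j): M ends in consumption, IX in query-codon gap,
  // IY in reference-residue gap.
  std::vector<double> M((n + 1) * (m + 1), NEG), IX((n + 1) * (m + 1), NEG),
      IY((n + 1) * (m + 1), NEG);
  // traceback: for M store consumption length c and emitted aa; for
  // IX/IY store predecessor matrix (0=M,1=IX,2=IY)
  std::vector<int> tbM((n + 1) * (m + 1), -1), tbMp((n + 1) * (m + 1), -1),
      tbMa((n + 1) * (m + 1), -1), tbX((n + 1) * (m + 1), -1),
      tbY((n + 1) * (m + 1), -1);
  auto id = [&](int i, int j) { return i * (m + 1) + j; };
  auto start = [&](int i, int j) { return (i == 0 && j == 0) ? 0.0 : NEG; };

  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i >= 3 && j >= 0) { // query-codon insertion gap
        double open = std::max(start(i - 3, j),
                               std::max(M[id(i - 3, j)], IY[id(i - 3, j)]));
        double ext = IX[id(i - 3, j)];
        double vo = open - (gap_open + gap_ext), ve = ext - gap_ext;
        if (vo >= ve) { IX[id(i, j)] = vo; tbX[id(i, j)] = (M[id(i-3,j)] >= start(i-3,j) && M[id(i-3,j)] >= IY[id(i-3,j)]) ? 0 : (start(i-3,j) >= IY[id(i-3,j)] ? 3 : 2); }
        else { IX[id(i, j)] = ve; tbX[id(i, j)] = 1; }
      }
      if (j >= 1) { // reference deletion gap
        double open = std::max(start(i, j - 1),
                               std::max(M[id(i, j - 1)], IX[id(i, j - 1)]));
        double ext = IY[id(i, j - 1)];
        double vo = open - (gap_open + gap_ext), ve = ext - gap_ext;
        if (vo >= ve) { IY[id(i, j)] = vo; tbY[id(i, j)] = (M[id(i,j-1)] >= start(i,j-1) && M[id(i,j-1)] >= IX[id(i,j-1)]) ? 0 : (start(i,j-1) >= IX[id(i,j-1)] ? 3 : 1); }
        else { IY[id(i, j)] = ve; tbY[id(i, j)] = 2; }
      }
      if (j >= 1) {
        double best = NEG; int bc = -1, bp = -1, ba = -1;
        for (int c = cmin; c <= cmax; ++c) {
          if (i < c) continue;
          double sc; int aa;
          repair(q, i, c, r[j - 1], caa, xa, S, sc, aa);
          double pen = fs_pen * std::abs(c - 3);
          double preM = M[id(i - c, j - 1)];
          double pre = std::max(start(i - c, j - 1),
                                std::max(preM,
                                         std::max(IX[id(i - c, j - 1)],
                                                  IY[id(i - c, j - 1)])));
          double v = pre + sc - pen;
          if (v > best) {
            best = v; bc = c; ba = aa;
            if (start(i - c, j - 1) >= preM &&
                start(i - c, j - 1) >= IX[id(i - c, j - 1)] &&
                start(i - c, j - 1) >= IY[id(i - c, j - 1)]) bp = 3;
            else if (preM >= IX[id(i - c, j - 1)] &&
                     preM >= IY[id(i - c, j - 1)]) bp = 0;
            else if (IX[id(i - c, j - 1)] >= IY[id(i - c, j - 1)]) bp = 1;
            else bp = 2;
          }
        }
        if (bc > 0) {
          M[id(i, j)] = best; tbM[id(i, j)] = bc; tbMp[id(i, j)] = bp;
          tbMa[id(i, j)] = ba;
        }
      }
    }
  }
  double sc = std::max(M[id(n, m)], std::max(IX[id(n, m)], IY[id(n, m)]));
  int cur = (M[id(n, m)] >= IX[id(n, m)] && M[id(n, m)] >= IY[id(n, m)]) ? 0
            : (IX[id(n, m)] >= IY[id(n, m)] ? 1 : 2);

  // traceback
  std::vector<int> col_type;   // 0 = match, 1 = query-codon insert, 2 = ref gap
  std::vector<int> col_aa;     // emitted aa (alphabet index), -1 for ref gap
  std::vector<int> col_ref;    // ref index (1-based) or 0
  std::vector<int> col_qpos;   // 1-based query offset of the chunk start, or 0
  std::vector<int> col_shift;  // consumption - 3 for match cols
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (cur == 3) break;
    if (cur == 0) {
      int c = tbM[id(i, j)];
      if (c < 0) stop("framebot traceback error");
      col_type.push_back(0);
      col_aa.push_back(tbMa[id(i, j)]);
      col_ref.push_back(j);
      col_qpos.push_back(i - c + 1);
      col_shift.push_back(c - 3);
      int p = tbMp[id(i, j)];
      i -= c; --j;
      cur = p;
    } else if (cur == 1) {
      int ci = codon_index(q[i - 3], q[i - 2], q[i - 1]);
      col_type.push_back(1);
      col_aa.push_back(ci < 0 ? xa : caa[ci]);
      col_ref.push_back(0);
      col_qpos.push_back(i - 2);
      col_shift.push_back(0);
      int p = tbX[id(i, j)];
      i -= 3;
      cur = p;
    } else {
      col_type.push_back(2);
      col_aa.push_back(-1);
      col_ref.push_back(j);
      col_qpos.push_back(0);
      col_shift.push_back(0);
      int p = tbY[id(i, j)];
      --j;
      cur = p;
    }
  }
  std::reverse(col_type.begin(), col_type.end());
  std::reverse(col_aa.begin(), col_aa.end());
  std::reverse(col_ref.begin(), col_ref.end());
  std::reverse(col_qpos.begin(), col_qpos.end());
  std::reverse(col_shift.begin(), col_shift.end());
  return List::create(_["score"] = sc, _["type"] = wrap(col_type),
                      _["aa"] = wrap(col_aa), _["ref"] = wrap(col_ref),
                      _["qpos"] = wrap(col_qpos), _["shift"] = wrap(col_shift));
}
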