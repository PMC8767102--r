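#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cctype>
#include <cstring>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise DP (Needleman-Wunsch / Smith-Waterman) with
// deterministic traceback (diagonal > up > left), plus batch helpers used by
// greedy centroid clustering and homolog recruitment. A gap of length L costs
// gap_open + L * gap_extend.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// residue -> substitution matrix index lookup built from dimnames
static void build_lookup(const NumericMatrix& sub, int* lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  List dn = sub.attr("dimnames");
  CharacterVector rn = dn[0];
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }
}

static std::vector<int> encode(const std::string& s, const int* lut) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[(unsigned char)std::toupper((unsigned char)s[i])];
    if (code < 0) stop("residue '%s' not present in substitution matrix",
                       std::string(1, s[i]).c_str());
    v[i] = code;
  }
  return v;
}

struct AlnResult {
  double score;
  std::string a_aln, b_aln;
};

// flattened row-major copy of the substitution matrix for fast lookup
struct SubFlat {
  std::vector<double> v;
  int ncol;
  SubFlat(const NumericMatrix& sub) : v(sub.nrow() * sub.ncol()), ncol(sub.ncol()) {
    for (int r = 0; r < sub.nrow(); ++r)
      for (int c = 0; c < sub.ncol(); ++c) v[r * ncol + c] = sub(r, c);
  }
  const double* row(int r) const { return &v[r * ncol]; }
};

// reusable DP buffers: interior cells are always overwritten, so only the
// boundary row/column needs (re)initialization per call
struct AlnWorkspace {
  std::vector<double> M, Ix, Iy;
  std::vector<unsigned char> tM, tIx, tIy;
  void ensure(size_t cells) {
    if (M.size() < cells) {
      M.resize(cells); Ix.resize(cells); Iy.resize(cells);
      tM.resize(cells); tIx.resize(cells); tIy.resize(cells);
    }
  }
};

// states: 0 = M (diag), 1 = Ix (gap in b, consumes a; "up"), 2 = Iy ("left")
static AlnResult align_core(const std::vector<int>& a, const std::vector<int>& b,
                            const SubFlat& sub, double open, double ext,
                            bool local,
                            const std::string& as, const std::string& bs,
                            AlnWorkspace& ws) {
  const int n = a.size(), m = b.size();
  const size_t cells = (size_t)(n + 1) * (m + 1);
  ws.ensure(cells);
  double* M = ws.M.data(); double* Ix = ws.Ix.data(); double* Iy = ws.Iy.data();
  unsigned char* tM = ws.tM.data(); unsigned char* tIx = ws.tIx.data();
  unsigned char* tIy = ws.tIy.data();
  #define IDX(i, j) ((size_t)(i) * (m + 1) + (j))

  // boundary initialization (interior cells are fully overwritten below)
  M[IDX(0, 0)] = local ? 0.0 : 0.0;
  Ix[IDX(0, 0)] = Iy[IDX(0, 0)] = NEG_INF;
  tM[IDX(0, 0)] = tIx[IDX(0, 0)] = tIy[IDX(0, 0)] = 3;
  for (int i = 1; i <= n; ++i) {
    M[IDX(i, 0)] = local ? 0.0 : NEG_INF;
    Iy[IDX(i, 0)] = NEG_INF;
    tM[IDX(i, 0)] = tIy[IDX(i, 0)] = 3;
    if (local) { Ix[IDX(i, 0)] = NEG_INF; tIx[IDX(i, 0)] = 3; }
    else { Ix[IDX(i, 0)] = -(open + i * ext); tIx[IDX(i, 0)] = (i == 1) ? 0 : 1; }
  }
  for (int j = 1; j <= m; ++j) {
    M[IDX(0, j)] = local ? 0.0 : NEG_INF;
    Ix[IDX(0, j)] = NEG_INF;
    tM[IDX(0, j)] = tIx[IDX(0, j)] = 3;
    if (local) { Iy[IDX(0, j)] = NEG_INF; tIy[IDX(0, j)] = 3; }
    else { Iy[IDX(0, j)] = -(open + j * ext); tIy[IDX(0, j)] = (j == 1) ? 0 : 2; }
  }

  double best = 0.0;
  int bi = 0, bj = 0;
  const double oe = open + ext;

  for (int i = 1; i <= n; ++i) {
    const double* srow = sub.row(a[i - 1]);
    const size_t prev = IDX(i - 1, 0), cur = IDX(i, 0);
    const double* Mp = M + prev; const double* Ixp = Ix + prev;
    const double* Iyp = Iy + prev;
    double* Mc = M + cur; double* Ixc = Ix + cur; double* Iyc = Iy + cur;
    unsigned char* tMc = tM + cur; unsigned char* tIxc = tIx + cur;
    unsigned char* tIyc = tIy + cur;
    for (int j = 1; j <= m; ++j) {
      const double s = srow[b[j - 1]];
      // M state: preference diagonal M > Ix > Iy
      double mx = Mp[j - 1]; unsigned char st = 0;
      if (Ixp[j - 1] > mx) { mx = Ixp[j - 1]; st = 1; }
      if (Iyp[j - 1] > mx) { mx = Iyp[j - 1]; st = 2; }
      double mval = mx + s;
      if (local && mval < 0.0) { mval = 0.0; st = 3; }
      Mc[j] = mval; tMc[j] = st;
      if (local && mval > best) { best = mval; bi = i; bj = j; }
      // Ix: gap in b (move up)
      double oM = Mp[j] - oe;
      double oX = Ixp[j] - ext;
      if (oM >= oX) { Ixc[j] = oM; tIxc[j] = 0; }
      else          { Ixc[j] = oX; tIxc[j] = 1; }
      // Iy: gap in a (move left)
      double pM = Mc[j - 1] - oe;
      double pY = Iyc[j - 1] - ext;
      if (pM >= pY) { Iyc[j] = pM; tIyc[j] = 0; }
      else          { Iyc[j] = pY; tIyc[j] = 2; }
    }
  }

  int ci, cj, cs;
  double score;
  if (local) {
    score = best; ci = bi; cj = bj; cs = 0;
    if (best <= 0.0) {
      AlnResult r; r.score = 0.0; r.a_aln = ""; r.b_aln = "";
      return r;
    }
  } else {
    double eM = M[IDX(n, m)], eX = Ix[IDX(n, m)], eY = Iy[IDX(n, m)];
    score = eM; cs = 0;
    if (eX > score) { score = eX; cs = 1; }
    if (eY > score) { score = eY; cs = 2; }
    ci = n; cj = m;
  }

  std::string ar, br;
  while (true) {
    if (!local && ci == 0 && cj == 0) break;
    if (cs == 0) {
      unsigned char p = tM[IDX(ci, cj)];
      if (local && p == 3) break;  // local start
      ar.push_back(as[ci - 1]); br.push_back(bs[cj - 1]);
      --ci; --cj; cs = p;
      if (!local && ci == 0 && cj == 0) break;
    } else if (cs == 1) {
      unsigned char p = tIx[IDX(ci, cj)];
      ar.push_back(as[ci - 1]); br.push_back('-');
      --ci; cs = p;
    } else {
      unsigned char p = tIy[IDX(ci, cj)];
      ar.push_back('-'); br.push_back(bs[cj - 1]);
      --cj; cs = p;
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(br.begin(), br.end());
  AlnResult r; r.score = score; r.a_aln = ar; r.b_aln = br;
  return r;
  #undef IDX
}

struct AlnStats {
  double score, identity, qcov;
  int matches, columns;
};

// identity over aligned columns excluding terminal-gap overhang (or over the
// shorter sequence when denom_shorter); qcov = query residues inside the
// aligned core / query length
static AlnStats stats_from(const AlnResult& r, int qlen, int tlen,
                           bool denom_shorter) {
  AlnStats st; st.score = r.score;
  const std::string& A = r.a_aln; const std::string& B = r.b_aln;
  int L = A.size();
  int first = -1, last = -1;
  for (int k = 0; k < L; ++k)
    if (A[k] != '-' && B[k] != '-') { if (first < 0) first = k; last = k; }
  if (first < 0) { st.identity = 0; st.qcov = 0; st.matches = 0; st.columns = 0; return st; }
  int matches = 0, cols = 0, qres = 0;
  for (int k = first; k <= last; ++k) {
    ++cols;
    if (A[k] != '-') ++qres;
    if (A[k] != '-' && B[k] != '-' &&
        std::toupper((unsigned char)A[k]) == std::toupper((unsigned char)B[k]))
      ++matches;
  }
  int denom = denom_shorter ? std::min(qlen, tlen) : cols;
  st.matches = matches; st.columns = cols;
  st.identity = denom > 0 ? (double)matches / denom : 0.0;
  st.qcov = qlen > 0 ? (double)qres / qlen : 0.0;
  return st;
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, NumericMatrix sub,
               double gap_open, double gap_extend, bool local,
               bool denom_shorter) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  int lut[256]; build_lookup(sub, lut);
  SubFlat sf(sub);
  AlnWorkspace ws;
  std::vector<int> av = encode(a, lut), bv = encode(b, lut);
  AlnResult r = align_core(av, bv, sf, gap_open, gap_extend, local, a, b, ws);
  AlnStats st = stats_from(r, a.size(), b.size(), denom_shorter);
  return List::create(_["score"] = r.score, _["a_aln"] = r.a_aln,
                      _["b_aln"] = r.b_aln, _["identity"] = st.identity,
                      _["qcov"] = st.qcov, _["matches"] = st.matches,
                      _["columns"] = st.columns);
}

// batch local/global scan of one query against many targets: score, identity,
// query coverage per target (used by homolog recruitment)
// [[Rcpp::export]]
DataFrame cpp_align_scan(std::string query, CharacterVector targets,
                         NumericMatrix sub, double gap_open, double gap_extend,
                         bool local, bool denom_shorter) {
  if (query.empty()) stop("sequences must be non-empty");
  int lut[256]; build_lookup(sub, lut);
  SubFlat sf(sub);
  AlnWorkspace ws;
  std::vector<int> qv = encode(query, lut);
  int n = targets.size();
  NumericVector score(n), identity(n), qcov(n);
  for (int t = 0; t < n; ++t) {
    std::string ts = as<std::string>(targets[t]);
    if (ts.empty()) stop("sequences must be non-empty");
    std::vector<int> tv = encode(ts, lut);
    AlnResult r = align_core(qv, tv, sf, gap_open, gap_extend, local, query, ts, ws);
    AlnStats st = stats_from(r, query.size(), ts.size(), denom_shorter);
    score[t] = st.score; identity[t] = st.identity; qcov[t] = st.qcov;
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["score"] = score, _["identity"] = identity,
                           _["qcov"] = qcov);
}

// greedy centroid clustering: sequences are pre-ordered by the caller; each
// joins the first existing centroid with global identity >= threshold, else
// founds a new cluster. A residue-composition bound prunes hopeless pairs.
// [[Rcpp::export]]
IntegerVector cpp_greedy_assign(CharacterVector seqs, double threshold,
                                NumericMatrix sub, double gap_open,
                                double gap_extend, bool denom_shorter) {
  int lut[256]; build_lookup(sub, lut);
  SubFlat sf(sub);
  AlnWorkspace ws;
  int n = seqs.size();
  IntegerVector assign(n);
  std::vector<int> centroids;               // indices into seqs
  std::vector<std::vector<int> > cent_enc;  // encoded centroid residues
  std::vector<std::array<int, 26> > cent_comp;
  std::vector<std::string> cent_str;

  for (int i = 0; i < n; ++i) {
    std::string si = as<std::string>(seqs[i]);
    std::vector<int> ei = encode(si, lut);
    std::array<int, 26> comp; comp.fill(0);
    for (char c : si) {
      int u = std::toupper((unsigned char)c) - 'A';
      if (u >= 0 && u < 26) ++comp[u];
    }
    int found = -1;
    for (size_t c = 0; c < centroids.size(); ++c) {
      int minlen = std::min(si.size(), cent_str[c].size());
      int overlap = 0;
      for (int k = 0; k < 26; ++k) overlap += std::min(comp[k], cent_comp[c][k]);
      if ((double)overlap / minlen < threshold) continue;  // identity bound
      AlnResult r = align_core(ei, cent_enc[c], sf, gap_open, gap_extend,
                               false, si, cent_str[c], ws);
      AlnStats st = stats_from(r, si.size(), cent_str[c].size(), denom_shorter);
      if (st.identity >= threshold) { found = c; break; }
    }
    if (found < 0) {
      centroids.push_back(i);
      cent_enc.push_back(ei);
      cent_comp.push_back(comp);
      cent_str.push_back(si);
      found = centroids.size() - 1;
    }
    assign[i] = found + 1;
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  IntegerVector cent(centroids.size());
  for (size_t c = 0; c < centroids.size(); ++c) cent[c] = centroids[c] + 1;
  assign.attr("centroids") = cent;
  return assign;
}

// p-distance matrix over rows of a multiple alignment:
// d(i,j) = mismatches / shared non-gap columns
// [[Rcpp::export]]
NumericMatrix cpp_pdist(CharacterVector rows) {
  int n = rows.size();
  std::vector<std::string> rs(n);
  for (int i = 0; i < n; ++i) {
    rs[i] = as<std::string>(rows[i]);
    for (char& c : rs[i]) {                  // normalize once: uppercase, '.'->'-'
      c = std::toupper((unsigned char)c);
      if (c == '.') c = '-';
    }
  }
  size_t L = rs.empty() ? 0 : rs[0].size();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    const char* ri = rs[i].data();
    for (int j = i + 1; j < n; ++j) {
      const char* rj = rs[j].data();
      int shared = 0, mism = 0;
      for (size_t k = 0; k < L; ++k) {
        const char a = ri[k], b = rj[k];
        if (a == '-' || b == '-') continue;
        ++shared;
        mism += (a != b);
      }
      if (shared == 0)
        stop("rows %d and %d share no aligned (non-gap) columns", i + 1, j + 1);
      d(i, j) = d(j, i) = (double)mism / shared;
    }
    Rcpp::checkUserInterrupt();
  }
  return d;
}

// local profile-HMM Viterbi in log2-odds space. Emission/transition inputs
// are already log2 (-Inf allowed). Sequence letters outside the 20-letter
// alphabet (X, ambiguity) emit with background frequency, i.e. 0 log-odds.
// Entry: uniform over match states, log2(1/M); exit free from any match.
static double viterbi_one(const NumericMatrix& mlo, const NumericMatrix& ilo,
                          const NumericMatrix& tlo, const std::string& seq,
                          const int* aidx) {
  const int M = mlo.nrow();
  const int L = seq.size();
  const double entry = -std::log2((double)M);
  // transitions out of node k live in row k (rows 0..M)
  std::vector<double> Vm(M + 1, NEG_INF), Vi(M + 1, NEG_INF), Vd(M + 1, NEG_INF);
  std::vector<double> pVm(M + 1), pVi(M + 1), pVd(M + 1);
  double best = NEG_INF;
  for (int i = 1; i <= L; ++i) {
    int a = aidx[(unsigned char)std::toupper((unsigned char)seq[i - 1])];
    std::swap(pVm, Vm); std::swap(pVi, Vi); std::swap(pVd, Vd);
    std::fill(Vm.begin(), Vm.end(), NEG_INF);
    std::fill(Vi.begin(), Vi.end(), NEG_INF);
    std::fill(Vd.begin(), Vd.end(), NEG_INF);
    for (int k = 1; k <= M; ++k) {
      double em = (a >= 0) ? mlo(k - 1, a) : 0.0;
      double v = entry;  // fresh local start at match k
      if (k > 1) {
        double c = pVm[k - 1] + tlo(k - 1, 0);           // M(k-1) -> M(k)
        if (c > v) v = c;
        c = pVi[k - 1] + tlo(k - 1, 3);                  // I(k-1) -> M(k)
        if (c > v) v = c;
        c = pVd[k - 1] + tlo(k - 1, 5);                  // D(k-1) -> M(k)
        if (c > v) v = c;
      }
      Vm[k] = em + v;
      if (Vm[k] > best) best = Vm[k];
      if (k < M) {
        double ei = (a >= 0) ? ilo(k - 1, a) : 0.0;
        double vi = pVm[k] + tlo(k, 1);                  // M(k) -> I(k)
        double c2 = pVi[k] + tlo(k, 4);                  // I(k) -> I(k)
        if (c2 > vi) vi = c2;
        Vi[k] = ei + vi;
      }
    }
    for (int k = 2; k <= M; ++k) {
      double vd = Vm[k - 1] + tlo(k - 1, 2);             // M(k-1) -> D(k)
      double c = Vd[k - 1] + tlo(k - 1, 6);              // D(k-1) -> D(k)
      if (c > vd) vd = c;
      Vd[k] = vd;
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_viterbi_batch(NumericMatrix match_log2odds,
                                NumericMatrix insert_log2odds,
                                NumericMatrix trans_log2,
                                CharacterVector seqs) {
  static const char* ALPHA = "ACDEFGHIKLMNPQRSTVWY";
  int aidx[256];
  for (int i = 0; i < 256; ++i) aidx[i] = -1;
  for (int i = 0; i < 20; ++i) aidx[(unsigned char)ALPHA[i]] = i;
  int n = seqs.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    std::string seq = as<std::string>(seqs[s]);
    if (seq.empty()) { out[s] = NEG_INF; continue; }
    out[s] = viterbi_one(match_log2odds, insert_log2odds, trans_log2, seq, aidx);
    if (s % 8 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
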