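#include <Rcpp.h>
using namespace Rcpp;

// Hot inner loops of the read-processing and clonotyping stages.
// Sequences arrive as plain character vectors; the caller is responsible for
// reverse-complementing the reverse mate before merging.

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *x = CHAR(STRING_ELT(a, i));
    const char *y = CHAR(STRING_ELT(b, i));
    size_t lx = strlen(x), ly = strlen(y);
    if (lx != ly) stop("hamming distance requires equal-length strings");
    int d = 0;
    for (size_t k = 0; k < lx; ++k) if (x[k] != y[k]) ++d;
    out[i] = d;
  }
  return out;
}

// Alignment score for the unequal-length identity path: global alignment with
// match = 1, mismatch = 0, gap = 0, whose optimum equals the longest common
// subsequence length.
// [[Rcpp::export]]
int cpp_lcs(std::string a, std::string b) {
  const size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All unordered pairs (i, j), 1-based, of equal-length strings whose Hamming
// percent identity strictly exceeds `threshold` (in percent).
// [[Rcpp::export]]
IntegerMatrix cpp_identity_edges(CharacterVector seqs, double threshold) {
  const int n = seqs.size();
  std::vector<const char*> p(n);
  size_t len = 0;
  for (int i = 0; i < n; ++i) {
    p[i] = CHAR(STRING_ELT(seqs, i));
    size_t li = strlen(p[i]);
    if (i == 0) len = li;
    else if (li != len) stop("cpp_identity_edges requires equal-length strings");
  }
  if (len == 0) stop("empty strings");
  // identity = 100*(len - d)/len > threshold  <=>  d < len*(1 - threshold/100)
  // (small epsilon keeps the strict inequality exact when the bound is integral)
  const double dmax_real = (double)len * (1.0 - threshold / 100.0) - 1e-9;
  std::vector<int> ii, jj;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = 0;
      const char *x = p[i], *y = p[j];
      for (size_t k = 0; k < len; ++k) {
        if (x[k] != y[k]) { ++d; if ((double)d >= dmax_real) break; }
      }
      if ((double)d < dmax_real) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}

// 3' quality trim: the last base is dropped while it falls below min_phred or
// the mean of the terminal window does; preceded by optional adapter
// read-through removal (leftmost read suffix matching a prefix of the adapter
// with <= 1 mismatch).
// [[Rcpp::export]]
List cpp_trim_reads(CharacterVector seqs, CharacterVector quals,
                    int min_phred, int window, String adapter) {
  const R_xlen_t n = seqs.size();
  if (quals.size() != n) stop("seq/qual length mismatch");
  std::string ad = adapter == NA_STRING ? std::string() : std::string(adapter.get_cstring());
  CharacterVector oseq(n), oqual(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    if (s.size() != q.size()) stop("read and quality lengths differ");
    // adapter first (it is sequence-defined), then quality
    if (!ad.empty() && !s.empty()) {
      for (size_t p = 0; p < s.size(); ++p) {
        size_t span = std::min(s.size() - p, ad.size());
        int mm = 0;
        for (size_t k = 0; k < span; ++k) if (s[p + k] != ad[k]) ++mm;
        if (mm <= 1) { s.resize(p); q.resize(p); break; }
      }
    }
    size_t len = s.size();
    while (len > 0) {
      if (q[len - 1] - 33 < min_phred) { --len; continue; }
      size_t w = std::min((size_t)window, len);
      int sum = 0;
      for (size_t k = len - w; k < len; ++k) sum += q[k] - 33;
      if ((double)sum / w >= (double)min_phred) break;
      --len;
    }
    s.resize(len); q.resize(len);
    oseq[i] = s; oqual[i] = q;
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual);
}

// FLASH-style overlap merge of a forward read with the reverse-complemented
// reverse read. Candidate overlaps o in [min_overlap, min(nf, nr)] compare the
// last o bases of fwd with the first o of rev_rc; qualifying overlaps
// (mismatch fraction <= max_mm_frac) are scored by match count, ties broken
// toward the smallest overlap. Disagreements resolve to the higher-quality
// base (forward wins quality ties).
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector fq,
                     CharacterVector rev_rc, CharacterVector rq,
                     int min_overlap, double max_mm_frac) {
  const R_xlen_t n = fwd.size();
  if (fq.size() != n || rev_rc.size() != n || rq.size() != n)
    stop("input vectors must have equal length");
  if (min_overlap < 1) stop("min_overlap must be >= 1");
  CharacterVector merged(n);
  IntegerVector olen(n), omm(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string f = as<std::string>(fwd[i]);
    std::string qf = as<std::string>(fq[i]);
    std::string r = as<std::string>(rev_rc[i]);
    std::string qr = as<std::string>(rq[i]);
    const int nf = f.size(), nr = r.size();
    int best_o = -1, best_m = -1;
    const int omax = std::min(nf, nr);
    for (int o = min_overlap; o <= omax; ++o) {
      int m = 0;
      const char *x = f.c_str() + (nf - o);
      for (int k = 0; k < o; ++k) if (x[k] == r[k]) ++m;
      if ((double)(o - m) / o <= max_mm_frac && m > best_m) { best_m = m; best_o = o; }
    }
    if (best_o < 0) {
      merged[i] = NA_STRING; olen[i] = NA_INTEGER; omm[i] = NA_INTEGER;
      continue;
    }
    const int o = best_o;
    std::string cons(o, 'N');
    for (int k = 0; k < o; ++k) {
      char fb = f[nf - o + k], rb = r[k];
      if (fb == rb) cons[k] = fb;
      else cons[k] = (qf[nf - o + k] >= qr[k]) ? fb : rb;
    }
    merged[i] = f.substr(0, nf - o) + cons + r.substr(o);
    olen[i] = o; omm[i] = o - best_m;
  }
  return List::create(_["seq"] = merged, _["overlap_len"] = olen,
                      _["mismatches"] = omm);
}
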