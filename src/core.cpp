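#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstring>
#include <functional>
using namespace Rcpp;

// 'N' is treated as matching nothing, including another 'N': ambiguity must
// never create a spurious zero-cost column.
static inline bool is_match(char a, char b) { return a == b && a != 'N'; }

// Advance one banded DP row by one subject character.
//
// prev holds the costs at the previous depth (length qlen+1, INF = d+1 stored
// in every cell whose true cost exceeds d); [plo,phi] is a covering interval
// of its finite cells (phi < plo when the row is dead). out receives the row
// at depth `depth` (the number of subject characters consumed, including ch);
// [*nlo,*nhi] covers its finite cells. Column 0 is the cost of aligning the
// subject prefix against an empty query prefix and is always charged.
//
// Finite cells of the new row can only arise from (a) the diagonal/vertical
// predecessors, confined to [plo, phi+1], or (b) horizontal chains seeded at
// column 0 or inside (a); the scan below covers exactly those and stops at
// the first saturated cell past phi+1.
static void row_advance_core(const int *prev, int plo, int phi,
                             const char *q, int qlen, char ch, int depth,
                             int d, int *out, int *nlo, int *nhi) {
  const int INF = d + 1;
  std::fill(out, out + qlen + 1, INF);
  int lo = INT_MAX, hi = -1;
  if (depth <= d) {
    out[0] = depth;
    lo = 0;
    hi = 0;
  }
  bool prev_alive = (phi >= plo);
  if (prev_alive || out[0] <= d) {
    int jstart = (out[0] <= d) ? 1 : std::max(1, plo);
    int jlimit = prev_alive ? std::min(qlen, phi + 1) : 0;
    for (int j = jstart; j <= qlen; ++j) {
      int best = INF;
      int pd = prev[j - 1];
      if (pd <= d) {
        int c = pd + (is_match(q[j - 1], ch) ? 0 : 1);
        if (c < best) best = c;
      }
      int pu = prev[j];
      if (pu <= d && pu + 1 < best) best = pu + 1;
      int hl = out[j - 1];
      if (hl <= d && hl + 1 < best) best = hl + 1;
      if (best <= d) {
        out[j] = best;
        if (j < lo) lo = j;
        if (j > hi) hi = j;
      } else if (j > jlimit) {
        break; // only horizontal sources remain and the chain just broke
      }
    }
  }
  *nlo = lo;
  *nhi = hi;
}

static void row_init_core(int qlen, bool anchor_start, int d, int *out,
                          int *lo, int *hi) {
  const int INF = d + 1;
  *lo = 0;
  if (anchor_start) {
    for (int j = 0; j <= qlen; ++j) out[j] = (j <= d) ? j : INF;
    *hi = std::min(qlen, d);
  } else {
    std::fill(out, out + qlen + 1, 0);
    *hi = qlen;
  }
}

// [[Rcpp::export]]
List cpp_row_init(int qlen, bool anchor_start, int d) {
  IntegerVector costs(qlen + 1);
  int lo, hi;
  std::vector<int> buf(qlen + 1);
  row_init_core(qlen, anchor_start, d, buf.data(), &lo, &hi);
  std::copy(buf.begin(), buf.end(), costs.begin());
  return List::create(_["costs"] = costs, _["lo"] = lo, _["hi"] = hi);
}

// [[Rcpp::export]]
List cpp_row_advance(IntegerVector prev, int plo, int phi, std::string query,
                     std::string ch, int depth, int d) {
  int qlen = query.size();
  if ((int)prev.size() != qlen + 1) stop("cost vector / query length mismatch");
  if (ch.size() != 1) stop("ch must be a single residue");
  IntegerVector out(qlen + 1);
  std::vector<int> pbuf(prev.begin(), prev.end()), obuf(qlen + 1);
  int lo, hi;
  row_advance_core(pbuf.data(), plo, phi, query.c_str(), qlen, ch[0], depth, d,
                   obuf.data(), &lo, &hi);
  std::copy(obuf.begin(), obuf.end(), out.begin());
  return List::create(_["costs"] = out, _["lo"] = lo, _["hi"] = hi);
}

// Threshold-limited pairwise cost. Returns the charged cost of the best
// alignment of subject against query under the policy, or -1 if it provably
// exceeds d.
// [[Rcpp::export]]
int cpp_pair_cost(std::string query, std::string subject, bool anchor_start,
                  bool anchor_end, int d) {
  int qlen = query.size(), slen = subject.size();
  const int INF = d + 1;
  std::vector<int> a(qlen + 1), b(qlen + 1);
  int lo, hi, nlo, nhi;
  row_init_core(qlen, anchor_start, d, a.data(), &lo, &hi);
  for (int i = 1; i <= slen; ++i) {
    row_advance_core(a.data(), lo, hi, query.c_str(), qlen, subject[i - 1], i,
                     d, b.data(), &nlo, &nhi);
    a.swap(b);
    lo = nlo;
    hi = nhi;
    if (lo > hi) return -1;
  }
  int res = INF;
  if (anchor_end) {
    res = a[qlen];
  } else {
    for (int j = lo; j <= hi; ++j)
      if (a[j] < res) res = a[j];
  }
  return (res <= d) ? res : -1;
}

// Full-matrix traceback for an accepted pair. Ties broken deterministically:
// diagonal over subject-gap (horizontal) over query-gap (vertical); with free
// end gaps the leftmost minimum of the final row is the alignment endpoint.
// [[Rcpp::export]]
List cpp_traceback(std::string query, std::string subject, bool anchor_start,
                   bool anchor_end) {
  int nq = query.size(), ns = subject.size();
  std::vector<int> T((size_t)(ns + 1) * (nq + 1));
  auto at = [&](int i, int j) -> int & { return T[(size_t)i * (nq + 1) + j]; };
  for (int j = 0; j <= nq; ++j) at(0, j) = anchor_start ? j : 0;
  for (int i = 1; i <= ns; ++i) {
    at(i, 0) = i;
    for (int j = 1; j <= nq; ++j) {
      int c = at(i - 1, j - 1) + (is_match(query[j - 1], subject[i - 1]) ? 0 : 1);
      int u = at(i - 1, j) + 1;
      int l = at(i, j - 1) + 1;
      at(i, j) = std::min(c, std::min(u, l));
    }
  }
  int jstar = nq;
  if (!anchor_end) {
    int best = INT_MAX;
    for (int j = 0; j <= nq; ++j)
      if (at(ns, j) < best) {
        best = at(ns, j);
        jstar = j;
      }
  }
  int cost = at(ns, jstar);
  std::string qrow, srow; // built in reverse
  int i = ns, j = jstar;
  while (i > 0 || j > 0) {
    if (i == 0) {
      if (!anchor_start) break; // remaining query prefix is a free end gap
      qrow.push_back(query[j - 1]);
      srow.push_back('-');
      --j;
    } else if (j == 0) {
      qrow.push_back('-');
      srow.push_back(subject[i - 1]);
      --i;
    } else {
      int sub = at(i - 1, j - 1) +
                (is_match(query[j - 1], subject[i - 1]) ? 0 : 1);
      if (at(i, j) == sub) {
        qrow.push_back(query[j - 1]);
        srow.push_back(subject[i - 1]);
        --i;
        --j;
      } else if (at(i, j) == at(i, j - 1) + 1) {
        qrow.push_back(query[j - 1]);
        srow.push_back('-');
        --j;
      } else {
        qrow.push_back('-');
        srow.push_back(subject[i - 1]);
        --i;
      }
    }
  }
  std::reverse(qrow.begin(), qrow.end());
  std::reverse(srow.begin(), srow.end());
  if (j > 0) { // free leading query characters (anchor_start = false)
    qrow.insert(0, query.substr(0, j));
    srow.insert(0, std::string(j, '-'));
  }
  if (jstar < nq) { // free trailing query characters (anchor_end = false)
    qrow.append(query.substr(jstar));
    srow.append(std::string(nq - jstar, '-'));
  }
  return List::create(_["query_row"] = qrow, _["subject_row"] = srow,
                      _["cost"] = cost);
}

// Longest common prefix of lexicographically adjacent sequences; lcp[0] = 0.
// [[Rcpp::export]]
IntegerVector cpp_lcp(CharacterVector seqs) {
  int n = seqs.size();
  IntegerVector lcp(n);
  for (int i = 1; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(seqs, i - 1));
    const char *b = CHAR(STRING_ELT(seqs, i));
    int m = 0;
    while (a[m] != '\0' && a[m] == b[m]) ++m;
    lcp[i] = m;
  }
  return lcp;
}

// Depth-first search of the implicit trie over the lex-sorted list.
//
// seqs must be in lexicographic order; lcp as from cpp_lcp; eligible marks
// candidates that may be reported. Returns the 1-based lex positions and
// costs of every eligible candidate whose policy cost against the query is
// <= its accept_radius, plus the number of row advances performed.
// [[Rcpp::export]]
List cpp_search(CharacterVector seqs, LogicalVector eligible,
                IntegerVector lcp, std::string query, bool anchor_start,
                bool anchor_end, int band_radius, IntegerVector accept_radius) {
  int n = seqs.size(), qlen = query.size();
  const int d = band_radius, INF = d + 1;
  std::vector<int> rows((size_t)(qlen + 1) * (qlen + 1));
  std::vector<int> los(qlen + 1), his(qlen + 1);
  row_init_core(qlen, anchor_start, d, rows.data(), &los[0], &his[0]);
  int pathlen = 0;   // characters of the reference path attempted so far
  bool dead = false; // band emptied at depth `pathlen` on the reference path
  int shared = 0;    // LCP of the reference path with the current candidate
  double nadv = 0;
  std::vector<int> hit_idx, hit_cost;
  for (int i = 0; i < n; ++i) {
    if (i > 0) shared = std::min(shared, lcp[i]);
    if (!eligible[i]) continue;
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = (int)std::strlen(s);
    if (len > qlen) continue; // candidates longer than the query never match
    if (dead && shared >= pathlen) continue; // shares the dead prefix: skip
    int resume = std::min(shared, dead ? pathlen - 1 : pathlen);
    bool ok = true;
    int depth = resume;
    for (int t = resume + 1; t <= len; ++t) {
      row_advance_core(&rows[(size_t)(t - 1) * (qlen + 1)], los[t - 1],
                       his[t - 1], query.c_str(), qlen, s[t - 1], t, d,
                       &rows[(size_t)t * (qlen + 1)], &los[t], &his[t]);
      ++nadv;
      depth = t;
      if (los[t] > his[t]) {
        ok = false;
        break;
      }
    }
    if (ok) {
      const int *row = &rows[(size_t)len * (qlen + 1)];
      int cost;
      if (anchor_end) {
        cost = row[qlen];
      } else {
        cost = INF;
        for (int j = los[len]; j <= his[len]; ++j)
          if (row[j] < cost) cost = row[j];
      }
      if (cost <= d && cost <= accept_radius[i]) {
        hit_idx.push_back(i + 1);
        hit_cost.push_back(cost);
      }
      pathlen = len;
      dead = false;
    } else {
      pathlen = depth;
      dead = true;
    }
    shared = pathlen;
  }
  return List::create(_["idx"] = wrap(hit_idx), _["cost"] = wrap(hit_cost),
                      _["n_advance"] = nadv);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1; // 'N' and anything else: k-mer is dropped
  }
}

static void spectrum_core(const char *s, int len, int k, int *counts) {
  for (int i = 0; i + k <= len; ++i) {
    int idx = 0;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      int c = base_code(s[i + t]);
      if (c < 0) {
        ok = false;
        break;
      }
      idx = (idx << 2) | c;
    }
    if (ok) ++counts[idx];
  }
}

// [[Rcpp::export]]
IntegerVector cpp_spectrum(std::string s, int k) {
  if (k < 1 || k > 8) stop("k must be between 1 and 8");
  int dim = 1 << (2 * k);
  IntegerVector counts(dim);
  spectrum_core(s.c_str(), (int)s.size(), k, INTEGER(counts));
  return counts;
}

// Balanced binary tree over lex-order intervals. Each node stores the
// element-wise min and max spectra of the sequences it covers plus the
// interval's length extremes. Node 1 is the root; child index 0 = leaf.
// [[Rcpp::export]]
List cpp_build_tree(CharacterVector seqs, int k) {
  int n = seqs.size();
  if (k < 1 || k > 6) stop("filter tree supports k between 1 and 6");
  int dim = 1 << (2 * k);
  if (n == 0)
    return List::create(_["k"] = k, _["n"] = 0);
  int nn = 2 * n - 1;
  if ((double)nn * dim > 8e7) stop("filter tree too large for this k; use a smaller k");
  IntegerVector lo(nn), hi(nn), left(nn), right(nn), minlen(nn), maxlen(nn);
  IntegerMatrix minspec(nn, dim), maxspec(nn, dim);
  int next = 0;
  // recursive lambda via explicit stack-free recursion
  std::function<int(int, int)> build = [&](int l, int r) -> int {
    int id = next++;
    lo[id] = l + 1; // 1-based for the R side
    hi[id] = r + 1;
    if (l == r) {
      const char *s = CHAR(STRING_ELT(seqs, l));
      int len = (int)std::strlen(s);
      std::vector<int> c(dim, 0);
      spectrum_core(s, len, k, c.data());
      for (int t = 0; t < dim; ++t) {
        minspec(id, t) = c[t];
        maxspec(id, t) = c[t];
      }
      minlen[id] = maxlen[id] = len;
      left[id] = right[id] = 0;
      return id;
    }
    int mid = (l + r) / 2;
    int a = build(l, mid);
    int b = build(mid + 1, r);
    for (int t = 0; t < dim; ++t) {
      minspec(id, t) = std::min(minspec(a, t), minspec(b, t));
      maxspec(id, t) = std::max(maxspec(a, t), maxspec(b, t));
    }
    minlen[id] = std::min(minlen[a], minlen[b]);
    maxlen[id] = std::max(maxlen[a], maxlen[b]);
    left[id] = a + 1;
    right[id] = b + 1;
    return id;
  };
  build(0, n - 1);
  return List::create(_["k"] = k, _["n"] = n, _["lo"] = lo, _["hi"] = hi,
                      _["left"] = left, _["right"] = right,
                      _["minlen"] = minlen, _["maxlen"] = maxlen,
                      _["minspec"] = minspec, _["maxspec"] = maxspec);
}

static inline int node_radius(double ratio, int mult, int len) {
  return mult * (int)std::floor(ratio * len + 1e-9);
}

// Prune decision for one node.
//
// Exact rule: every covered spectrum dominates the node min spectrum, so
// pos(minspec - qspec) > k*d_max (the radius of the node's LONGEST member)
// implies pos(member - qspec) > k*d_member for every member -- no true hit
// is ever lost.
//
// Approximate mode instead evaluates the node at d_min, the radius of its
// SHORTEST member, and adds an optimistic shared-k-mer bound: the number of
// k-mers any member can share with the query is at most
// sum_i min(maxspec_i, qspec_i), while a true hit of length minlen needs at
// least (minlen - k + 1) - k*d_min of them. At a leaf both reduce to the
// exact pair test; in mixed-length subtrees longer members (whose own radius
// exceeds d_min) can be discarded (documented lossy).
static bool prune_core(const int *minspec, const int *maxspec, int dim,
                       const int *qspec, int k, int d_max, int d_min,
                       int minlen, bool approximate) {
  long posdiff = 0;
  for (int t = 0; t < dim; ++t) {
    int d = minspec[t] - qspec[t];
    if (d > 0) posdiff += d;
  }
  int dnode = approximate ? d_min : d_max;
  if (posdiff > (long)k * dnode) return true;
  if (approximate) {
    long shared_ub = 0;
    for (int t = 0; t < dim; ++t)
      shared_ub += std::min(maxspec[t], qspec[t]);
    if (shared_ub < (long)(minlen - k + 1) - (long)k * d_min) return true;
  }
  return false;
}

// [[Rcpp::export]]
bool cpp_prune_node(List tree, int node, IntegerVector qspec, double ratio,
                    int mult, bool approximate) {
  int k = as<int>(tree["k"]);
  IntegerMatrix minspec = tree["minspec"], maxspec = tree["maxspec"];
  IntegerVector maxlen = tree["maxlen"], minlen = tree["minlen"];
  int dim = minspec.ncol();
  if ((int)qspec.size() != dim) stop("query spectrum has wrong k");
  std::vector<int> mn(dim), mx(dim);
  for (int t = 0; t < dim; ++t) {
    mn[t] = minspec(node - 1, t);
    mx[t] = maxspec(node - 1, t);
  }
  return prune_core(mn.data(), mx.data(), dim, INTEGER(qspec), k,
                    node_radius(ratio, mult, maxlen[node - 1]),
                    node_radius(ratio, mult, minlen[node - 1]),
                    minlen[node - 1], approximate);
}

// Traverse the filter tree; returns, per lex position, whether the candidate
// survives the k-mer screen for this query.
// [[Rcpp::export]]
LogicalVector cpp_filter_tree(List tree, IntegerVector qspec, double ratio,
                              int mult, bool approximate) {
  int n = as<int>(tree["n"]);
  LogicalVector out(n); // FALSE-initialised
  if (n == 0) return out;
  int k = as<int>(tree["k"]);
  IntegerMatrix minspec = tree["minspec"], maxspec = tree["maxspec"];
  IntegerVector lo = tree["lo"], hi = tree["hi"], left = tree["left"],
                right = tree["right"], maxlen = tree["maxlen"],
                minlen = tree["minlen"];
  int dim = minspec.ncol();
  if ((int)qspec.size() != dim) stop("query spectrum has wrong k");
  const int *q = INTEGER(qspec);
  std::vector<int> stack;
  stack.push_back(1);
  std::vector<int> mn(dim), mx(dim);
  while (!stack.empty()) {
    int id = stack.back();
    stack.pop_back();
    int r = id - 1;
    for (int t = 0; t < dim; ++t) {
      mn[t] = minspec(r, t);
      mx[t] = maxspec(r, t);
    }
    if (prune_core(mn.data(), mx.data(), dim, q, k,
                   node_radius(ratio, mult, maxlen[r]),
                   node_radius(ratio, mult, minlen[r]), minlen[r],
                   approximate))
      continue;
    if (left[r] == 0) {
      out[lo[r] - 1] = true;
    } else {
      stack.push_back(left[r]);
      stack.push_back(right[r]);
    }
  }
  return out;
}
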