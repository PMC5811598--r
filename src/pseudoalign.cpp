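#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <cstdint>
using namespace Rcpp;

// Minimal k-mer pseudoaligner with equivalence-class semantics: the
// compatibility set of a read is the intersection of the transcript sets of
// all its indexed k-mers (k-mers absent from the index are skipped; k-mers
// containing non-ACGT characters are never indexed).  A read is unmapped if
// no k-mer is indexed or the intersection is empty.  Equal compatibility
// sets are memoized so they share one equivalence-class identifier, in
// order of first appearance.

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// [[Rcpp::export]]
List cpp_pseudoalign(CharacterVector transcripts, int k,
                     CharacterVector payloads) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // index: k-mer -> sorted vector of transcript indices (1-based)
  std::unordered_map<uint64_t, std::vector<int> > index;
  const int nt = transcripts.size();
  for (int t = 0; t < nt; ++t) {
    SEXP s = STRING_ELT(transcripts, t);
    const char *seq = CHAR(s);
    const int L = LENGTH(s);
    if (L < k)
      stop("transcript %d is shorter than k = %d", t + 1, k);
    uint64_t val = 0;
    int run = 0;
    for (int i = 0; i < L; ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        std::vector<int> &v = index[val];
        if (v.empty() || v.back() != t + 1) v.push_back(t + 1);
      }
    }
  }

  const int n = payloads.size();
  IntegerVector ec(n);
  std::map<std::vector<int>, int> class_id;
  std::vector<std::vector<int> > classes;
  std::vector<int> cur, tmp;

  for (int i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(payloads, i);
    const char *seq = CHAR(s);
    const int L = LENGTH(s);
    cur.clear();
    bool any = false, dead = false;
    uint64_t val = 0;
    int run = 0;
    for (int p = 0; p < L && !dead; ++p) {
      int c = base_code(seq[p]);
      if (c < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
          index.find(val);
      if (it == index.end()) continue;  // unindexed k-mer: skipped
      const std::vector<int> &set = it->second;
      if (!any) {
        cur = set;
        any = true;
      } else {
        tmp.clear();
        std::set_intersection(cur.begin(), cur.end(), set.begin(), set.end(),
                              std::back_inserter(tmp));
        cur.swap(tmp);
        if (cur.empty()) dead = true;
      }
    }
    if (!any || cur.empty()) {
      ec[i] = 0;  // unmapped
      continue;
    }
    std::map<std::vector<int>, int>::iterator it = class_id.find(cur);
    if (it == class_id.end()) {
      classes.push_back(cur);
      it = class_id.insert(std::make_pair(cur, (int)classes.size())).first;
    }
    ec[i] = it->second;
  }

  List cls(classes.size());
  for (size_t j = 0; j < classes.size(); ++j)
    cls[j] = IntegerVector(classes[j].begin(), classes[j].end());
  return List::create(_["ec"] = ec, _["classes"] = cls);
}
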