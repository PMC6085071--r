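#include <Rcpp.h>
using namespace Rcpp;

// Ungapped scanning primitives for the mismatch-tolerant mapper.
// Sequences arrive as uppercase DNA character strings; any base that is not an
// exact character match counts as a mismatch, so 'N' never matches A/C/G/T.

// End-to-end scan of one read over one strand: every offset where the whole
// read aligns with <= max_mm mismatches (early exit once over budget).
static void scan_e2e_one(const char* read, int lr, const char* contig,
                         int lc, int max_mm,
                         std::vector<int>& starts, std::vector<int>& mms) {
  for (int s = 0; s + lr <= lc; ++s) {
    int mm = 0;
    for (int j = 0; j < lr; ++j) {
      if (read[j] != contig[s + j] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) {
      starts.push_back(s);
      mms.push_back(mm);
    }
  }
}

// Batch end-to-end scan: both strands of every read against one contig.
// `reads_rc` holds the reverse complement of each read. Returns parallel
// vectors (read index 1-based, 0-based start, strand "+"/"-", mismatches).
// [[Rcpp::export]]
List scan_batch_e2e_cpp(CharacterVector reads, CharacterVector reads_rc,
                        std::string contig, int max_mm) {
  const char* cs = contig.c_str();
  const int lc = contig.size();
  std::vector<int> ridx, starts, mms;
  std::vector<int> strands;  // 0 = +, 1 = -
  std::vector<int> st, mm;
  for (int i = 0; i < reads.size(); ++i) {
    const char* fw = CHAR(STRING_ELT(reads, i));
    const char* rv = CHAR(STRING_ELT(reads_rc, i));
    const int lr = LENGTH(STRING_ELT(reads, i));
    for (int strand = 0; strand < 2; ++strand) {
      st.clear(); mm.clear();
      scan_e2e_one(strand == 0 ? fw : rv, lr, cs, lc, max_mm, st, mm);
      for (size_t k = 0; k < st.size(); ++k) {
        ridx.push_back(i + 1);
        starts.push_back(st[k]);
        strands.push_back(strand);
        mms.push_back(mm[k]);
      }
    }
  }
  return List::create(_["read"] = wrap(ridx), _["start"] = wrap(starts),
                      _["strand"] = wrap(strands),
                      _["mismatches"] = wrap(mms));
}

struct LocalBest {
  int len = -1, mm = 0, start = 0, strand = 0;
};

// Local (soft-clip) scan of one read/strand: ungapped placement of a read
// substring ("core") of length >= min_core with <= max_mm mismatches. For
// each diagonal d (contig position aligned with read position 0; may be
// negative when the read hangs off the contig start) a two-pointer sweep
// enumerates every maximal window with <= max_mm mismatches; the best is
// kept by longest core, then fewest mismatches, then smallest contig start,
// then + strand before -.
static void scan_local_one(const char* read, int lr, const char* contig,
                           int lc, int max_mm, int min_core, int strand,
                           LocalBest& best) {
  for (int d = -(lr - min_core); d <= lc - min_core; ++d) {
    int jlo = std::max(0, -d);
    int jhi = std::min(lr, lc - d);  // exclusive
    if (jhi - jlo < min_core) continue;
    int left = jlo, mm = 0;
    for (int right = jlo; right < jhi; ++right) {
      if (read[right] != contig[d + right]) ++mm;
      while (mm > max_mm) {
        if (read[left] != contig[d + left]) --mm;
        ++left;
      }
      int len = right - left + 1;
      if (len < min_core) continue;
      int start = d + left;
      bool better = len > best.len ||
        (len == best.len &&
         (mm < best.mm ||
          (mm == best.mm && (start < best.start ||
                             (start == best.start &&
                              strand < best.strand)))));
      if (better) {
        best.len = len; best.mm = mm; best.start = start;
        best.strand = strand;
      }
    }
  }
}

// Batch local scan: the single best soft-clipped placement of each read on
// one contig (both strands), or no entry when no core reaches min_core.
// [[Rcpp::export]]
List scan_batch_local_cpp(CharacterVector reads, CharacterVector reads_rc,
                          std::string contig, int max_mm, int min_core) {
  const char* cs = contig.c_str();
  const int lc = contig.size();
  std::vector<int> ridx, starts, cores, mms, strands;
  for (int i = 0; i < reads.size(); ++i) {
    const char* fw = CHAR(STRING_ELT(reads, i));
    const char* rv = CHAR(STRING_ELT(reads_rc, i));
    const int lr = LENGTH(STRING_ELT(reads, i));
    if (lr < min_core) continue;
    LocalBest best;
    scan_local_one(fw, lr, cs, lc, max_mm, min_core, 0, best);
    scan_local_one(rv, lr, cs, lc, max_mm, min_core, 1, best);
    if (best.len >= min_core) {
      ridx.push_back(i + 1);
      starts.push_back(best.start);
      cores.push_back(best.len);
      mms.push_back(best.mm);
      strands.push_back(best.strand);
    }
  }
  return List::create(_["read"] = wrap(ridx), _["start"] = wrap(starts),
                      _["core_len"] = wrap(cores),
                      _["mismatches"] = wrap(mms),
                      _["strand"] = wrap(strands));
}
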