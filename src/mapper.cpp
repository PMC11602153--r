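#include <Rcpp.h>
using namespace Rcpp;

// End-to-end Hamming placement of short reads against a small set of tRNA
// references. For each read, every offset of every reference is scored by
// mismatch count (N matches nothing); the best placement wins. Reads whose
// best score exceeds max_mismatch are unmapped; reads with two or more
// best-score placements are multimapped. Early abandon at max_mismatch + 1
// keeps the scan cheap without affecting best/tie bookkeeping below the
// threshold.

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector refs,
                        int max_mismatch) {
  const int nreads = reads.size(), nrefs = refs.size();
  std::vector<std::string> refstr(nrefs);
  for (int j = 0; j < nrefs; ++j) refstr[j] = as<std::string>(refs[j]);

  IntegerVector best_ref(nreads, NA_INTEGER), best_start(nreads, NA_INTEGER),
      best_mm(nreads, NA_INTEGER), n_best(nreads, 0);

  for (int i = 0; i < nreads; ++i) {
    const std::string rd = as<std::string>(reads[i]);
    const int lr = (int)rd.size();
    int best = max_mismatch + 1, ties = 0, bref = -1, bstart = -1;
    for (int j = 0; j < nrefs; ++j) {
      const std::string& rf = refstr[j];
      const int lref = (int)rf.size();
      if (lr > lref) continue;
      for (int off = 0; off + lr <= lref; ++off) {
        int mm = 0;
        for (int k = 0; k < lr; ++k) {
          char c = rd[k];
          if (c == 'N' || c != rf[off + k]) {
            if (++mm > max_mismatch) break;
          }
        }
        if (mm > max_mismatch) continue;
        if (mm < best) {
          best = mm; ties = 1; bref = j; bstart = off + 1;  // 1-based
        } else if (mm == best) {
          ++ties;
        }
      }
    }
    if (best <= max_mismatch) {
      best_ref[i] = bref + 1;
      best_start[i] = bstart;
      best_mm[i] = best;
      n_best[i] = ties;
    }
  }
  return DataFrame::create(_["ref"] = best_ref, _["start"] = best_start,
                           _["mismatches"] = best_mm, _["n_best"] = n_best);
}
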