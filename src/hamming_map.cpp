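#include <Rcpp.h>
using namespace Rcpp;

// Ungapped sliding comparison of each read (both strands) against a tiled
// copy of the repeat unit. Candidate start offsets are 1..unit_length, so a
// placement inside a tandem array is reported in canonical single-unit
// coordinates (position modulo unit length). Ties go to the forward strand,
// then to the smallest offset.
//
// [[Rcpp::export]]
List hamming_map_cpp(CharacterVector reads, CharacterVector reads_rc,
                     std::string tile, int unit_length) {
  int n = reads.size();
  IntegerVector best_start(n), best_mm(n);
  CharacterVector best_strand(n);
  const char *t = tile.c_str();
  int tlen = (int) tile.size();
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = as<std::string>(reads_rc[i]);
    int rl = (int) fwd.size();
    int bm = rl + 1, bs = 0;
    bool brev = false;
    for (int s = 0; s < 2; ++s) {
      const char *r = s ? rev.c_str() : fwd.c_str();
      for (int off = 0; off < unit_length && off + rl <= tlen; ++off) {
        int mm = 0;
        const char *tp = t + off;
        for (int k = 0; k < rl; ++k) {
          if (r[k] != tp[k]) {
            if (++mm >= bm) break;
          }
        }
        if (mm < bm) { bm = mm; bs = off; brev = (s == 1); }
      }
    }
    best_start[i] = bs + 1;
    best_mm[i] = bm;
    best_strand[i] = brev ? "-" : "+";
  }
  return List::create(_["start"] = best_start,
                      _["mismatches"] = best_mm,
                      _["strand"] = best_strand);
}
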