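#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Exact mismatch-counting placement of reads over every offset of every
// chromosome, both strands.  No index, no heuristics: candidate generation
// must be exhaustive so that the retention policy layered on top in R
// ("best stratum, keep if <= m placements") is exact and oracle-testable.
// The inner loop aborts an offset as soon as the mismatch budget v_max is
// exceeded, which keeps the scan close to linear in genome length for
// small v_max.

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return r;
}

// [[Rcpp::export(name = ".cpp_place_candidates")]]
DataFrame cpp_place_candidates(CharacterVector reads, CharacterVector chroms,
                               int v_max) {
  if (chroms.size() == 0) stop("empty genome");
  std::vector<std::string> genome(chroms.size());
  for (int c = 0; c < chroms.size(); ++c)
    genome[c] = as<std::string>(chroms[c]);

  std::vector<int> out_read, out_chrom, out_start, out_mm;
  std::vector<int> out_strand;  // 1 = forward, 0 = reverse

  for (int r = 0; r < reads.size(); ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const std::string rev = revcomp(fwd);
    const int rl = (int)fwd.size();
    for (int c = 0; c < (int)genome.size(); ++c) {
      const std::string& g = genome[c];
      const int n = (int)g.size() - rl + 1;
      for (int strand = 0; strand < 2; ++strand) {
        const char* q = (strand == 0 ? fwd.c_str() : rev.c_str());
        for (int off = 0; off < n; ++off) {
          int mm = 0;
          const char* t = g.c_str() + off;
          for (int j = 0; j < rl; ++j) {
            if (q[j] != t[j] && ++mm > v_max) break;
          }
          if (mm <= v_max) {
            out_read.push_back(r + 1);
            out_chrom.push_back(c + 1);
            out_start.push_back(off);
            out_strand.push_back(strand == 0 ? 1 : 0);
            out_mm.push_back(mm);
          }
        }
      }
    }
  }
  return DataFrame::create(_["read_index"] = out_read,
                           _["chrom_index"] = out_chrom,
                           _["start"] = out_start,
                           _["forward"] = out_strand,
                           _["mismatches"] = out_mm);
}
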