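#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Fitting alignment: the whole read aligns to a substring of the amplicon
// reference (free reference flanks). Affine gaps with Biostrings' cost
// convention: a gap of length L costs gapOpening + L * gapExtension
// (match +1, mismatch -1, gapOpening 3, gapExtension 1).
static const int NEG = -100000000;
static const int MATCH = 1, MISMATCH = -1, GAP_OPEN1 = 4, GAP_EXT = 1;

// [[Rcpp::export]]
List fit_align_batch_cpp(std::vector<std::string> reads, std::string ref) {
  int n = ref.size();
  List out(reads.size());
  size_t max_m = 0;
  for (size_t r = 0; r < reads.size(); ++r)
    max_m = std::max(max_m, reads[r].size());
  size_t stride = n + 1;
  // flat state matrices reused across reads: M (aligned pair), Ix (gap in
  // ref / insertion in read), Iy (gap in read / deletion)
  std::vector<int> Mv((max_m + 1) * stride), Ixv((max_m + 1) * stride),
      Iyv((max_m + 1) * stride);
  int *M = Mv.data(), *Ix = Ixv.data(), *Iy = Iyv.data();
#define AT(A, i, j) A[(size_t)(i) * stride + (j)]
  for (size_t r = 0; r < reads.size(); ++r) {
    const std::string &x = reads[r];
    int m = x.size();
    for (int j = 0; j <= n; ++j) {
      AT(M, 0, j) = 0;  // free start anywhere in ref
      AT(Ix, 0, j) = NEG;
      AT(Iy, 0, j) = NEG;
    }
    for (int i = 1; i <= m; ++i) {
      AT(M, i, 0) = NEG;
      AT(Ix, i, 0) = -(GAP_OPEN1 + (i - 1) * GAP_EXT);
      AT(Iy, i, 0) = NEG;
      const char xi = x[i - 1];
      const int *Mp = &AT(M, i - 1, 0), *Ixp = &AT(Ix, i - 1, 0),
                *Iyp = &AT(Iy, i - 1, 0);
      int *Mc = &AT(M, i, 0), *Ixc = &AT(Ix, i, 0), *Iyc = &AT(Iy, i, 0);
      for (int j = 1; j <= n; ++j) {
        int s = (xi == ref[j - 1]) ? MATCH : MISMATCH;
        int prev = std::max(Mp[j - 1], std::max(Ixp[j - 1], Iyp[j - 1]));
        Mc[j] = (prev <= NEG / 2) ? NEG : prev + s;
        int opn = std::max(Mp[j], Iyp[j]);
        Ixc[j] = std::max(opn <= NEG / 2 ? NEG : opn - GAP_OPEN1,
                          Ixp[j] <= NEG / 2 ? NEG : Ixp[j] - GAP_EXT);
        int opn2 = std::max(Mc[j - 1], Ixc[j - 1]);
        Iyc[j] = std::max(opn2 <= NEG / 2 ? NEG : opn2 - GAP_OPEN1,
                          Iyc[j - 1] <= NEG / 2 ? NEG : Iyc[j - 1] - GAP_EXT);
      }
    }
    // best end: whole read consumed; do not end inside a deletion
    int best = NEG, bj = 0, bstate = 0;
    for (int j = 0; j <= n; ++j) {
      if (AT(M, m, j) > best) { best = AT(M, m, j); bj = j; bstate = 0; }
      if (AT(Ix, m, j) > best) { best = AT(Ix, m, j); bj = j; bstate = 1; }
    }
    // traceback
    std::vector<int> ref_pos, ins_pos;
    std::vector<char> base, ins_base;
    int i = m, j = bj, state = bstate, matches = 0;
    while (i > 0) {
      if (state == 0) {  // M
        int s = (x[i - 1] == ref[j - 1]) ? MATCH : MISMATCH;
        if (s == MATCH) ++matches;
        ref_pos.push_back(j);
        base.push_back(x[i - 1]);
        int prev = AT(M, i, j) - s;
        --i; --j;
        if (i == 0) break;
        if (AT(M, i, j) == prev) state = 0;
        else if (AT(Ix, i, j) == prev) state = 1;
        else state = 2;
      } else if (state == 1) {  // Ix: read char inserted after ref pos j
        ins_pos.push_back(j);
        ins_base.push_back(x[i - 1]);
        int cur = AT(Ix, i, j);
        --i;
        if (i == 0) break;
        if (AT(Ix, i, j) == cur + GAP_EXT) state = 1;
        else if (AT(M, i, j) == cur + GAP_OPEN1) state = 0;
        else state = 2;
      } else {  // Iy: deletion, ref char skipped in read
        ref_pos.push_back(j);
        base.push_back('-');
        int cur = AT(Iy, i, j);
        --j;
        if (AT(Iy, i, j) == cur + GAP_EXT) state = 2;
        else if (AT(M, i, j) == cur + GAP_OPEN1) state = 0;
        else state = 1;
      }
    }
    std::reverse(ref_pos.begin(), ref_pos.end());
    std::reverse(base.begin(), base.end());
    std::reverse(ins_pos.begin(), ins_pos.end());
    std::reverse(ins_base.begin(), ins_base.end());
    CharacterVector basev(base.size()), insv(ins_base.size());
    for (size_t k = 0; k < base.size(); ++k)
      basev[k] = std::string(1, base[k]);
    for (size_t k = 0; k < ins_base.size(); ++k)
      insv[k] = std::string(1, ins_base[k]);
    out[r] = List::create(
        Named("ref_pos") = wrap(ref_pos), Named("base") = basev,
        Named("ins_pos") = wrap(ins_pos), Named("ins_base") = insv,
        Named("score") = best,
        Named("identity") = m > 0 ? (double)matches / m : 0.0);
  }
  return out;
}
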