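#include <Rcpp.h>
using namespace Rcpp;

static inline char comp(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// FLASH-style pairwise merge. Read 2 is reverse-complemented and both
// orientations are scanned exhaustively:
//   innie: suffix of read1 overlaps prefix of rc(read2); merged sequence is
//          the union (fragment longer than one read);
//   outie: prefix of read1 overlaps suffix of rc(read2), the read-through
//          case of a fragment shorter than the reads; merged sequence is
//          the overlap consensus only (the overhangs are read-through into
//          primer/adapter and are discarded).
// The admissible overlap (length >= min_overlap, mismatch density <=
// max_mismatch_density) maximizing matches wins; ties prefer innie, then
// the longer overlap. Disagreeing overlap bases take the higher-quality
// call (tie -> read 1).
// [[Rcpp::export]]
CharacterVector merge_pairs_cpp(CharacterVector read1, CharacterVector read2,
                                CharacterVector qual1, CharacterVector qual2,
                                int min_overlap, double max_mismatch_density) {
  int n = read1.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(read1[i]);
    std::string b0 = as<std::string>(read2[i]);
    std::string qa = as<std::string>(qual1[i]);
    std::string qb0 = as<std::string>(qual2[i]);
    int L1 = a.size(), L2 = b0.size();
    std::string b(L2, 'N'), qb(L2, '!');
    for (int j = 0; j < L2; ++j) {
      b[j] = comp(b0[L2 - 1 - j]);
      qb[j] = (j < (int)qb0.size()) ? qb0[L2 - 1 - j] : '!';
    }
    int omax = std::min(L1, L2);
    int best_o = -1, best_m = -1;
    bool best_innie = true;
    for (int o = min_overlap; o <= omax; ++o) {
      // innie: a[L1-o .. L1) vs b[0 .. o)
      int m = 0;
      {
        const char *pa = a.data() + (L1 - o);
        for (int j = 0; j < o; ++j)
          if (pa[j] == b[j]) ++m;
      }
      if ((double)(o - m) <= max_mismatch_density * o) {
        if (m > best_m || (m == best_m && !best_innie) ||
            (m == best_m && best_innie && o > best_o)) {
          best_m = m; best_o = o; best_innie = true;
        }
      }
      // outie: a[0 .. o) vs b[L2-o .. L2)
      m = 0;
      {
        const char *pb = b.data() + (L2 - o);
        for (int j = 0; j < o; ++j)
          if (a[j] == pb[j]) ++m;
      }
      if ((double)(o - m) <= max_mismatch_density * o) {
        if (m > best_m || (m == best_m && !best_innie && o > best_o)) {
          best_m = m; best_o = o; best_innie = false;
        }
      }
    }
    if (best_o < 0) {
      out[i] = NA_STRING;
      continue;
    }
    int o = best_o;
    std::string merged;
    if (best_innie) {
      merged.reserve(L1 + L2 - o);
      merged.append(a, 0, L1 - o);
      for (int j = 0; j < o; ++j) {
        char ca = a[L1 - o + j], cb = b[j];
        if (ca == cb) {
          merged.push_back(ca);
        } else {
          char qca = (L1 - o + j < (int)qa.size()) ? qa[L1 - o + j] : '!';
          merged.push_back(qb[j] > qca ? cb : ca);
        }
      }
      merged.append(b, o, L2 - o);
    } else {
      merged.reserve(o);
      for (int j = 0; j < o; ++j) {
        char ca = a[j], cb = b[L2 - o + j];
        if (ca == cb) {
          merged.push_back(ca);
        } else {
          char qca = (j < (int)qa.size()) ? qa[j] : '!';
          merged.push_back(qb[L2 - o + j] > qca ? cb : ca);
        }
      }
    }
    out[i] = merged;
  }
  return out;
}
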