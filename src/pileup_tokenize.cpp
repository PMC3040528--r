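#include <Rcpp.h>
#include <cctype>
#include <map>
#include <string>
using namespace Rcpp;

// Single-pass tokenizer for the classic SAMtools pileup read-bases string.
// Grammar handled per token:
//   '.' / ','           reference call (forward / reverse strand)
//   ACGTN / acgtn       alternate base call
//   '*'                 deletion placeholder (counts as a call token; the
//                       deletion itself was recorded on the anchoring base)
//   '^X'                read start; consumes the mapping-quality char X
//   '$'                 read end; consumed, not a call
//   '+n<seq>' / '-n<seq>'  insertion/deletion attached to the preceding call
// Token conservation: the number of call tokens must equal the depth column.

// [[Rcpp::export]]
List pileup_tokenize_cpp(CharacterVector bases, CharacterVector ref) {
  R_xlen_t n = bases.size();
  List out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(bases, i));
    char refb = std::toupper(CHAR(STRING_ELT(ref, i))[0]);
    int ref_count = 0, star_count = 0, tokens = 0;
    std::map<std::string, int> snv, ins, del;
    size_t j = 0, len = std::strlen(s);
    bool bad = false;
    while (j < len) {
      char c = s[j];
      if (c == '.' || c == ',') {
        ++ref_count; ++tokens; ++j;
      } else if (c == '^') {
        if (j + 1 >= len) { bad = true; break; }
        j += 2;  // consume mapping-quality character
      } else if (c == '$') {
        ++j;
      } else if (c == '*') {
        ++star_count; ++tokens; ++j;
      } else if (c == '+' || c == '-') {
        size_t k = j + 1;
        int num = 0;
        while (k < len && std::isdigit((unsigned char)s[k])) {
          num = num * 10 + (s[k] - '0'); ++k;
        }
        if (num == 0 || k + num > len) { bad = true; break; }
        std::string seq(s + k, s + k + num);
        if (c == '+') ++ins[seq]; else ++del[seq];
        j = k + num;
      } else {
        char u = std::toupper((unsigned char)c);
        if (u == 'A' || u == 'C' || u == 'G' || u == 'T' || u == 'N') {
          if (u == refb) { bad = true; break; }  // explicit base equal to ref
          ++snv[std::string(1, u)];
          ++tokens; ++j;
        } else {
          bad = true; break;
        }
      }
    }
    int snv_total = 0;
    CharacterVector snv_names(snv.size()), ins_names(ins.size()), del_names(del.size());
    IntegerVector snv_counts(snv.size()), ins_counts(ins.size()), del_counts(del.size());
    int t = 0;
    for (auto &kv : snv) { snv_names[t] = kv.first; snv_counts[t] = kv.second; snv_total += kv.second; ++t; }
    snv_counts.attr("names") = snv_names;
    t = 0;
    for (auto &kv : ins) { ins_names[t] = kv.first; ins_counts[t] = kv.second; ++t; }
    ins_counts.attr("names") = ins_names;
    t = 0;
    for (auto &kv : del) { del_names[t] = kv.first; del_counts[t] = kv.second; ++t; }
    del_counts.attr("names") = del_names;
    out[i] = List::create(
      _["ref_count"] = ref_count,
      _["snv_counts"] = snv_counts,
      _["insertion_counts"] = ins_counts,
      _["deletion_counts"] = del_counts,
      _["deletion_placeholders"] = star_count,
      _["tokens"] = tokens,
      _["malformed"] = bad);
  }
  return out;
}
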