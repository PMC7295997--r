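#include <Rcpp.h>
using namespace Rcpp;

// One diffusion + evaporation step on a toroidal grid.
// Each cell keeps (1 - df) of its content and sends df/8 to each of its
// 8 toroidal neighbors; the whole field is then scaled by (1 - ef).
// Mass-conserving for ef = 0. Raw-pointer, column-wise traversal: this is
// the innermost kernel of every simulation tick.
// [[Rcpp::export(name = ".diffuse_decay_cpp")]]
NumericMatrix diffuse_decay_cpp(NumericMatrix field, double df, double ef) {
  const int nr = field.nrow(), nc = field.ncol();
  NumericMatrix out(nr, nc);
  const double keep = 1.0 - df, share = df / 8.0, scale = 1.0 - ef;
  const double *x = field.begin();
  double *o = out.begin();
  for (int j = 0; j < nc; ++j) {
    const int jl = (j == 0) ? nc - 1 : j - 1;
    const int jr = (j == nc - 1) ? 0 : j + 1;
    const double *cl = x + (size_t)jl * nr;
    const double *cc = x + (size_t)j * nr;
    const double *cr = x + (size_t)jr * nr;
    double *oc = o + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const int iu = (i == 0) ? nr - 1 : i - 1;
      const int id = (i == nr - 1) ? 0 : i + 1;
      const double nb = cl[iu] + cl[i] + cl[id] + cc[iu] + cc[id]
                      + cr[iu] + cr[i] + cr[id];
      oc[i] = (keep * cc[i] + share * nb) * scale;
    }
  }
  return out;
}
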