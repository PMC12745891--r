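#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kaiser-Bessel convolution gridding of non-Cartesian (radial) k-space
// samples onto an oversampled Cartesian grid.  Coordinates are in grid
// units with DC at 0; indices wrap modulo G (the oversampled grid size).

static inline double kb_i0(double x) {
  return R::bessel_i(x, 0.0, 1.0);
}

// [[Rcpp::export]]
ComplexMatrix grid_radial_cpp(NumericVector kx, NumericVector ky,
                              ComplexVector s, int G, double width,
                              double beta) {
  const int n = kx.size();
  if (ky.size() != n || s.size() != n)
    stop("kx, ky and s must have equal length");
  const double half = width / 2.0;

  // kernel lookup table over u in [0, half]
  const int TAB = 4096;
  std::vector<double> tab(TAB + 1);
  for (int i = 0; i <= TAB; ++i) {
    double u = half * i / TAB;
    double t = 1.0 - (u / half) * (u / half);
    tab[i] = kb_i0(beta * std::sqrt(t > 0 ? t : 0.0));
  }
  auto kern = [&](double u) -> double {
    double au = std::fabs(u);
    if (au >= half) return 0.0;
    double pos = au / half * TAB;
    int i = (int)pos;
    double f = pos - i;
    return tab[i] * (1.0 - f) + tab[i + 1 < TAB ? i + 1 : TAB] * f;
  };

  ComplexMatrix out(G, G);
  std::vector<double> re(G * (size_t)G, 0.0), im(G * (size_t)G, 0.0);

  for (int q = 0; q < n; ++q) {
    double x = kx[q], y = ky[q];
    double sr = s[q].r, si = s[q].i;
    int x0 = (int)std::ceil(x - half), x1 = (int)std::floor(x + half);
    int y0 = (int)std::ceil(y - half), y1 = (int)std::floor(y + half);
    for (int mx = x0; mx <= x1; ++mx) {
      double wx = kern(x - mx);
      if (wx == 0.0) continue;
      int ix = ((mx % G) + G) % G;
      for (int my = y0; my <= y1; ++my) {
        double w = wx * kern(y - my);
        if (w == 0.0) continue;
        int iy = ((my % G) + G) % G;
        size_t off = (size_t)iy * G + ix;  // column-major: row ix, col iy
        re[off] += w * sr;
        im[off] += w * si;
      }
    }
  }
  for (size_t i = 0; i < (size_t)G * G; ++i) {
    out[i].r = re[i];
    out[i].i = im[i];
  }
  return out;
}
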