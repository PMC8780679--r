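#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) integration of a particle on a
// tabulated 1-D landscape under a harmonic umbrella bias.
//
// Ito SDE:  dz = [ -beta * D(z) * (dG'(z) + k (z - c)) + D'(z) ] dt
//               + sqrt(2 D(z) dt) xi
// The D'(z) spurious-drift term makes the stationary density Boltzmann,
// rho(z) ~ exp(-beta (G(z) + k/2 (z-c)^2)), for position-dependent D.
//
// grid must be uniform; grad_g, d_val, d_grad are dG/dz, D and dD/dz
// tabulated on it. Uses R's RNG (seed with set.seed() before calling).
// Boundaries at [zmin, zmax] are reflecting.
// [[Rcpp::export]]
NumericVector langevin_window_cpp(NumericVector grid,
                                  NumericVector grad_g,
                                  NumericVector d_val,
                                  NumericVector d_grad,
                                  double z0, double center,
                                  double force_constant, double beta,
                                  double dt, int n_steps, int n_discard,
                                  int save_stride,
                                  double zmin, double zmax,
                                  bool spurious_drift) {
  const int ng = grid.size();
  const double h = grid[1] - grid[0];
  const double g0 = grid[0];
  const int n_keep = (n_steps - n_discard) / save_stride;
  NumericVector out(n_keep);

  double z = z0;
  int isave = 0;
  for (int s = 1; s <= n_steps; ++s) {
    double x = (z - g0) / h;
    int i = (int)std::floor(x);
    if (i < 0) i = 0;
    if (i > ng - 2) i = ng - 2;
    double w = x - (double)i;
    double gg = grad_g[i] * (1.0 - w) + grad_g[i + 1] * w;
    double D  = d_val[i]  * (1.0 - w) + d_val[i + 1]  * w;
    double dD = d_grad[i] * (1.0 - w) + d_grad[i + 1] * w;

    double drift = -beta * D * (gg + force_constant * (z - center));
    if (spurious_drift) drift += dD;
    z += drift * dt + std::sqrt(2.0 * D * dt) * R::norm_rand();

    // reflecting boundaries
    while (z < zmin || z > zmax) {
      if (z < zmin) z = 2.0 * zmin - z;
      if (z > zmax) z = 2.0 * zmax - z;
    }
    if (s > n_discard && (s - n_discard) % save_stride == 0) {
      out[isave++] = z;
    }
  }
  return out;
}
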