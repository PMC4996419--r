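#include <Rcpp.h>
using namespace Rcpp;

// Exact (direct-method) simulation of the birth-death process whose
// mean-field limit is the two-strain cross-feeding ODE. Counts x, y live on
// a lattice with system size omega individuals at carrying capacity;
// densities are x/omega, y/omega. Reactions:
//   X birth: r_x * x * g_x * max(0, 1 - (x + c*y)/omega)
//   X death: delta * x
//   Y birth: r_y * y * g_y * max(0, 1 - (c*x + y)/omega)
//   Y death: delta * y
// with g_x = (y/omega + a)/(y/omega + a + kappa) and
//      g_y = (beta*x/omega + a)/(beta*x/omega + a + kappa).
// The max(0, .) clamp is the minimal non-negative rate choice above
// carrying capacity. Uses R's RNG so set.seed() gives bit-identical runs.
// [[Rcpp::export]]
NumericMatrix gillespie_core(double r_x, double r_y, double kappa,
                             double beta, double delta, double a, double c,
                             double omega, double x0, double y0,
                             double t_max, double record_dt) {
  int n_rec = (int)(t_max / record_dt) + 1;
  NumericMatrix out(n_rec, 3);
  double x = x0, y = y0, t = 0.0;
  int irec = 0;

  RNGScope scope;
  while (irec < n_rec) {
    double gx = (y / omega + a) / (y / omega + a + kappa);
    double gy = (beta * x / omega + a) / (beta * x / omega + a + kappa);
    double lx = 1.0 - (x + c * y) / omega;
    double ly = 1.0 - (c * x + y) / omega;
    double bx = r_x * x * gx * (lx > 0.0 ? lx : 0.0);
    double by = r_y * y * gy * (ly > 0.0 ? ly : 0.0);
    double dx = delta * x;
    double dy = delta * y;
    double total = bx + by + dx + dy;

    double t_next;
    if (total <= 0.0) {
      t_next = t_max + record_dt;  // absorbed: only sampling remains
    } else {
      t_next = t + R::exp_rand() / total;
    }
    // emit all sample points passed by this jump
    while (irec < n_rec && irec * record_dt <= t_next) {
      out(irec, 0) = irec * record_dt;
      out(irec, 1) = x;
      out(irec, 2) = y;
      ++irec;
    }
    if (t_next > t_max) break;
    t = t_next;
    double u = unif_rand() * total;
    if (u < bx)                x += 1.0;
    else if (u < bx + dx)      x -= 1.0;
    else if (u < bx + dx + by) y += 1.0;
    else                       y -= 1.0;
    if (x < 0.0) x = 0.0;  // unreachable by construction; belt and braces
    if (y < 0.0) y = 0.0;
  }
  // fill any remaining sample points (horizon reached while absorbed)
  while (irec < n_rec) {
    out(irec, 0) = irec * record_dt;
    out(irec, 1) = x;
    out(irec, 2) = y;
    ++irec;
  }
  colnames(out) = CharacterVector::create("time", "x", "y");
  return out;
}
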