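#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the four-variable optorepressilator
//   x'  : light-inducible LacI, dx'/dt = beta_prime(t) - alpha x'
//   x,y,z: ring repressors; (x + x') represses y.
// beta_prime holds one value per step, sampled at the step's left endpoint.
// Every record_every-th state is stored (the initial state always is), so the
// caller must pass a step count divisible by record_every.
// [[Rcpp::export]]
NumericMatrix euler_opto(NumericVector init, double alpha, double beta,
                         double n, NumericVector beta_prime, double dt,
                         int record_every) {
  const int n_steps = beta_prime.size();
  if (n_steps % record_every != 0)
    stop("step count must be divisible by record_every");
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix out(n_rec, 4);
  double x = init[0], y = init[1], z = init[2], xp = init[3];
  out(0, 0) = x; out(0, 1) = y; out(0, 2) = z; out(0, 3) = xp;
  int r = 1;
  for (int k = 0; k < n_steps; ++k) {
    const double dx  = beta / (1.0 + std::pow(z, n)) - alpha * x;
    const double dy  = beta / (1.0 + std::pow(x + xp, n)) - alpha * y;
    const double dz  = beta / (1.0 + std::pow(y, n)) - alpha * z;
    const double dxp = beta_prime[k] - alpha * xp;
    x += dt * dx;
    y += dt * dy;
    z += dt * dz;
    xp += dt * dxp;
    if (!(R_finite(x) && R_finite(y) && R_finite(z) && R_finite(xp)))
      stop("non-finite state at step %d (t = %g h)", k + 1, (k + 1) * dt);
    if ((k + 1) % record_every == 0) {
      out(r, 0) = x; out(r, 1) = y; out(r, 2) = z; out(r, 3) = xp;
      ++r;
    }
  }
  return out;
}
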