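// Continuous-attractor grid-module integrator.
//
// The recurrent kernel is translation-invariant on the N x N torus (one
// kernel image per presynaptic preferred direction, shifted by l*e_theta),
// so the recurrent drive W.g is computed as four FFT circular convolutions
// per module per step instead of a dense N^2 x N^2 matrix-vector product.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigmoid_mat(const mat& x, double kg) {
  return 1.0 / (1.0 + exp(-kg * x));
}

// Recurrent input for one module: sum over the four direction
// subpopulations of kernel (x) masked-activity circular convolutions.
static mat recurrent_drive(const mat& g, const cx_cube& Khat,
                           const cube& masks, int m) {
  const uword N = g.n_rows;
  cx_mat acc(N, N, fill::zeros);
  for (int d = 0; d < 4; ++d)
    acc += Khat.slice(4 * m + d) % fft2(g % masks.slice(d));
  return real(ifft2(acc));
}

// Fast path used by the integrator: each Gaussian of the
// difference-of-Gaussians kernel factorizes over the two torus axes (the
// minimal-image wrap is applied per axis), so the per-direction circular
// convolution is a pair of 1-D circulant matrix products,
//   K_d (*) g_d = (a Cy_b) g_d Cx_b - (a Cy_1) g_d Cx_1,
// with the direction's l-shift folded into the shifted axis circulant.
// Csep holds, per module and direction, the four circulants
// [a*Cy_b, Cx_b, a*Cy_1, Cx_1] (16 slices per module, built in R).
static mat recurrent_drive_sep(const mat& g, const cube& Csep,
                               const cube& masks, int m) {
  const uword N = g.n_rows;
  mat acc(N, N, fill::zeros);
  for (int d = 0; d < 4; ++d) {
    const mat gd = g % masks.slice(d);
    const uword o = 16 * m + 4 * d;
    acc += Csep.slice(o) * gd * Csep.slice(o + 1);
    acc -= Csep.slice(o + 2) * gd * Csep.slice(o + 3);
  }
  return acc;
}

// [[Rcpp::export]]
arma::mat recurrent_input_cpp(const arma::mat& g, const arma::cx_cube& Khat,
                              const arma::cube& masks, int module0) {
  return recurrent_drive(g, Khat, masks, module0);
}

static inline double wrapN(double z, double N) {
  z = std::fmod(z + N / 2.0, N);
  if (z < 0) z += N;
  return z - N / 2.0;
}

// Pattern displacement of g relative to the reference snapshot (via the
// peak of the circular cross-correlation nearest the previous estimate).
// The pattern is lattice-periodic, so the correlation has many equivalent
// peaks; tracking the one nearest the previous displacement keeps the
// estimate continuous. Returns the unwrapped displacement (dx, dy).
static void track_displacement(const mat& g, const cx_mat& Ghat_ref,
                               double prev_dx, double prev_dy, int window,
                               double& out_dx, double& out_dy) {
  const int N = g.n_rows;
  mat C = real(ifft2(fft2(g) % conj(Ghat_ref)));
  // search the window around the previous (wrapped) displacement
  int cx0 = (int)std::lround(prev_dx);
  int cy0 = (int)std::lround(prev_dy);
  double best = -datum::inf;
  int bx = 0, by = 0;
  for (int ddy = -window; ddy <= window; ++ddy)
    for (int ddx = -window; ddx <= window; ++ddx) {
      int ix = ((cx0 + ddx) % N + N) % N;
      int iy = ((cy0 + ddy) % N + N) % N;
      // correlation at shift (sx, sy): C(sy, sx) with row = y shift
      if (C(iy, ix) > best) {
        best = C(iy, ix);
        bx = cx0 + ddx;
        by = cy0 + ddy;
      }
    }
  // quadratic sub-pixel refinement along each axis
  auto Cat = [&](int sy, int sx) {
    return C(((sy % N) + N) % N, ((sx % N) + N) % N);
  };
  double c0 = Cat(by, bx);
  double dxm = Cat(by, bx - 1), dxp = Cat(by, bx + 1);
  double dym = Cat(by - 1, bx), dyp = Cat(by + 1, bx);
  double sub_x = 0.0, sub_y = 0.0;
  double denx = dxm - 2.0 * c0 + dxp;
  double deny = dym - 2.0 * c0 + dyp;
  if (std::abs(denx) > 1e-12) sub_x = 0.5 * (dxm - dxp) / denx;
  if (std::abs(deny) > 1e-12) sub_y = 0.5 * (dym - dyp) / deny;
  if (std::abs(sub_x) > 1.0) sub_x = 0.0;
  if (std::abs(sub_y) > 1.0) sub_y = 0.0;
  out_dx = bx + sub_x;
  out_dy = by + sub_y;
}

// Run M grid modules (shared sheet size N) over a velocity sequence with
// forward-Euler dynamics, optionally driving an attached place-cell sheet
// (scalar weight per module) with competitive Hebbian weight learning.
//
// g      : N x N x M activity cube (state, modified copy returned)
// Csep   : N x N x 16M separable kernel circulants (module-major; see
//          recurrent_drive_sep)
// masks  : N x N x 4 direction membership masks (0/1)
// Ex, Ey : N x N components of each neuron's preferred-direction unit vector
// vx, vy : planar velocity per step (m/s)
// alpha, kg, i0, tau, nm : per-module velocity gain, sigmoid steepness,
//                      tonic excitatory drive, time constant, period count
// w, kp, lr : place weights (length M), place steepness, learning rate
//             (kp <= 0 disables the place sheet; lr <= 0 freezes w)
// record_every : thinning for recorded outputs (0 = record nothing)
// track  : rows of (0-based column-major cell index, 0-based module index)
//          whose activities are recorded at each recorded step; module
//          index M (one past the grid modules) tracks the place sheet
//
// Recorded per kept step: place winner (0-based row-major index), per-module
// unwrapped pattern displacement (dx, dy in neurons, relative to the state
// at entry), tracked cell activities. dwtrace holds ||w_after - w_before||
// per step when learning is on.
// [[Rcpp::export]]
Rcpp::List stack_run_cpp(arma::cube g,
                         const arma::cube& Csep,
                         const arma::cube& masks,
                         const arma::mat& Ex, const arma::mat& Ey,
                         const arma::vec& vx, const arma::vec& vy,
                         const arma::vec& alpha, const arma::vec& kg,
                         const arma::vec& i0,
                         double dt, const arma::vec& tau,
                         const arma::vec& nm,
                         arma::vec w, double kp, double lr,
                         int record_every,
                         const arma::imat& track) {
  const int N = g.n_rows;
  const int M = g.n_slices;
  const int T = vx.n_elem;
  const int n_rec = (record_every > 0) ? T / record_every : 0;
  const int n_trk = track.n_rows;
  const bool do_place = (kp > 0.0);
  const bool learn = do_place && (lr > 0.0);

  ivec winners(n_rec, fill::value(-1));
  mat disp(n_rec, 2 * M, fill::zeros);
  mat tracked(n_rec, n_trk, fill::zeros);
  vec dwtrace(learn ? T : 0, fill::zeros);
  bool w_reinit = false;

  // displacement-tracking references and state
  std::vector<cx_mat> Ghat_ref(M);
  std::vector<int> window(M);
  vec cur_dx(M, fill::zeros), cur_dy(M, fill::zeros);
  if (record_every > 0)
    for (int m = 0; m < M; ++m) {
      Ghat_ref[m] = fft2(g.slice(m));
      int win = (int)std::floor(N / nm(m) / 2.0) - 1;
      window[m] = std::max(2, win);
    }

  mat p;
  for (int t = 0; t < T; ++t) {
    for (int m = 0; m < M; ++m) {
      mat u = recurrent_drive_sep(g.slice(m), Csep, masks, m);
      u += alpha(m) * (Ex * vx(t) + Ey * vy(t)) + i0(m);
      g.slice(m) += (dt / tau(m)) * (-g.slice(m) + sigmoid_mat(u, kg(m)));
    }

    const bool rec = (record_every > 0) && ((t + 1) % record_every == 0);

    if (do_place && (learn || rec)) {
      mat up(N, N, fill::zeros);
      for (int m = 0; m < M; ++m) up += w(m) * g.slice(m);
      p = 1.0 / (1.0 + exp(kp * (up.max() - up)));
      if (learn) {
        vec w_old = w;
        for (int m = 0; m < M; ++m)
          w(m) += lr * accu(p % (g.slice(m) - p * w(m)));
        w.transform([](double x) { return x < 0.0 ? 0.0 : x; });
        double nw = norm(w);
        if (nw <= 0.0) {
          w.fill(1.0 / std::sqrt(static_cast<double>(M)));
          w_reinit = true;
        } else {
          w /= nw;
        }
        dwtrace(t) = norm(w - w_old);
      }
    }

    if (rec) {
      const int r = (t + 1) / record_every - 1;
      for (int m = 0; m < M; ++m) {
        double ndx, ndy;
        track_displacement(g.slice(m), Ghat_ref[m], cur_dx(m), cur_dy(m),
                           window[m], ndx, ndy);
        cur_dx(m) = ndx;
        cur_dy(m) = ndy;
        disp(r, 2 * m) = ndx;
        disp(r, 2 * m + 1) = ndy;
      }
      if (do_place) {
        // strict-> scan in row-major order: ties break to the lowest
        // row-major index
        double best = -datum::inf;
        int bi = 0;
        for (int rr = 0; rr < N; ++rr)
          for (int cc = 0; cc < N; ++cc)
            if (p(rr, cc) > best) { best = p(rr, cc); bi = rr * N + cc; }
        winners(r) = bi;
      }
      for (int k = 0; k < n_trk; ++k)
        // module index M refers to the place sheet (when attached)
        tracked(r, k) = (track(k, 1) == M && do_place)
                          ? p(track(k, 0))
                          : g.slice(track(k, 1))(track(k, 0));
    }
  }

  if (do_place && p.n_elem == 0) {
    mat up(N, N, fill::zeros);
    for (int m = 0; m < M; ++m) up += w(m) * g.slice(m);
    p = 1.0 / (1.0 + exp(kp * (up.max() - up)));
  }

  return Rcpp::List::create(
      Rcpp::Named("g") = g,
      Rcpp::Named("w") = w,
      Rcpp::Named("winners") = winners,
      Rcpp::Named("disp") = disp,
      Rcpp::Named("tracked") = tracked,
      Rcpp::Named("dwtrace") = dwtrace,
      Rcpp::Named("p") = p,
      Rcpp::Named("w_reinit") = w_reinit);
}
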