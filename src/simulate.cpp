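#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama loop for the non-reciprocal adaptive Kuramoto system.
//
// variant: 0 = dense, 1 = sparse (adjacency-weighted), 2 = freq_adaptive.
// Noise (sigma > 0) is drawn with norm_rand() so the R-level RNG seed
// controls it. Velocities returned are the deterministic right-hand side
// (the snapshot quantity the escape predictor uses); the stochastic
// increment sigma*sqrt(dt)*N(0,1) is added on top of vel*dt.
//
// Records R and R2 every step (length n_steps + 1, including the initial
// state). Full-resolution phases/velocities are returned as n x
// (n_steps + 1) matrices (one contiguous column per step); coupling frames
// are strided.
// [[Rcpp::export]]
List simulate_cpp(NumericVector theta0,
                  NumericMatrix k0,
                  NumericVector omega,
                  double eps1, double eps2,
                  double beta1, double beta2,
                  double sigma,
                  int variant,
                  double gamma0, double alpha,
                  Nullable<NumericMatrix> adjacency,
                  double dt,
                  int n_steps,
                  int record_stride,
                  bool store_phases,
                  bool store_velocities,
                  bool store_couplings) {
  const int n = theta0.size();
  const double TWOPI = 2.0 * M_PI;

  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> k(n * n);         // column-major like R
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      k[i + n * j] = k0(i, j);

  std::vector<double> adj;
  std::vector<double> deg(n, 0.0);
  const bool sparse = (variant == 1);
  if (sparse) {
    if (adjacency.isNull()) stop("sparse variant requires an adjacency matrix");
    NumericMatrix a(adjacency);
    adj.assign(n * n, 0.0);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        adj[i + n * j] = a(i, j);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) deg[i] += adj[i + n * j];
      if (deg[i] < 1.0) stop("sparse variant requires every degree >= 1");
    }
  }

  const double sb1 = std::sin(beta1), cb1 = std::cos(beta1);
  const double sb2 = std::sin(beta2), cb2 = std::cos(beta2);
  const double sa = std::sin(alpha), ca = std::cos(alpha);

  NumericVector R_series(n_steps + 1), R2_series(n_steps + 1);
  const int n_frames = n_steps / record_stride + 1;
  NumericMatrix theta_full = store_phases
    ? NumericMatrix(n, n_steps + 1) : NumericMatrix(0, 0);
  NumericMatrix vel_full = store_velocities
    ? NumericMatrix(n, n_steps + 1) : NumericMatrix(0, 0);
  NumericVector k_frames = store_couplings
    ? NumericVector(Dimension(n, n, n_frames)) : NumericVector(0);
  IntegerVector frame_steps(store_couplings ? n_frames : 0);

  std::vector<double> vel(n), sin_th(n), cos_th(n);
  const double noise_amp = sigma * std::sqrt(dt);

  RNGScope scope; // sync with R's RNG for norm_rand()

  double* theta_full_p = store_phases ? REAL(theta_full) : nullptr;
  double* vel_full_p = store_velocities ? REAL(vel_full) : nullptr;

  int frame_idx = 0;
  for (int step = 0; step <= n_steps; ++step) {
    double sr = 0.0, si = 0.0, s2r = 0.0, s2i = 0.0;
    for (int i = 0; i < n; ++i) {
      sin_th[i] = std::sin(th[i]);
      cos_th[i] = std::cos(th[i]);
      sr += cos_th[i];
      si += sin_th[i];
      // e^{2 i theta} from double-angle identities
      s2r += cos_th[i] * cos_th[i] - sin_th[i] * sin_th[i];
      s2i += 2.0 * sin_th[i] * cos_th[i];
    }
    R_series[step]  = std::sqrt(sr * sr + si * si) / n;
    R2_series[step] = std::sqrt(s2r * s2r + s2i * s2i) / n;

    // deterministic phase velocities
    if (variant == 2) { // freq_adaptive
      for (int i = 0; i < n; ++i) {
        const double si_ = sin_th[i], ci_ = cos_th[i];
        double acc = 0.0;
        for (int j = 0; j < n; ++j) {
          // sin(theta_i - theta_j + alpha)
          double sij = si_ * cos_th[j] - ci_ * sin_th[j];
          double cij = ci_ * cos_th[j] + si_ * sin_th[j];
          acc += k[i + n * j] * (gamma0 - (sij * ca + cij * sa));
        }
        // j == i term contributes k_ii * gamma0 = 0 (zero diagonal)
        vel[i] = omega[i] + acc / n;
      }
    } else if (sparse) {
      for (int i = 0; i < n; ++i) {
        const double si_ = sin_th[i], ci_ = cos_th[i];
        double acc = 0.0;
        for (int j = 0; j < n; ++j)
          acc += adj[i + n * j] * k[i + n * j] *
                 (sin_th[j] * ci_ - cos_th[j] * si_);
        vel[i] = omega[i] + acc / deg[i];
      }
    } else {
      for (int i = 0; i < n; ++i) {
        const double si_ = sin_th[i], ci_ = cos_th[i];
        double acc = 0.0;
        for (int j = 0; j < n; ++j)
          acc += k[i + n * j] * (sin_th[j] * ci_ - cos_th[j] * si_);
        vel[i] = omega[i] + acc / n;
      }
    }

    if (store_phases)
      std::copy(th.begin(), th.end(), theta_full_p + (size_t)n * step);
    if (store_velocities)
      std::copy(vel.begin(), vel.end(), vel_full_p + (size_t)n * step);
    if (store_couplings && step % record_stride == 0) {
      std::copy(k.begin(), k.end(),
                REAL(k_frames) + (size_t)n * n * frame_idx);
      frame_steps[frame_idx] = step;
      ++frame_idx;
    }
    if (step == n_steps) break;

    // coupling update: target is -sin(theta_i - theta_j + beta); split into
    // strict triangles so the inner loops carry no branch
    for (int j = 0; j < n; ++j) {
      const double sj = sin_th[j], cj = cos_th[j];
      double* kcol = &k[n * j];
      for (int i = 0; i < j; ++i) { // upper triangle (Hebbian, eps1/beta1)
        double sij = sin_th[i] * cj - cos_th[i] * sj;
        double cij = cos_th[i] * cj + sin_th[i] * sj;
        double dk = -eps1 * (kcol[i] + sij * cb1 + cij * sb1);
        if (sparse) dk *= adj[i + n * j];
        kcol[i] += dt * dk;
      }
      for (int i = j + 1; i < n; ++i) { // lower triangle (anti-Hebbian)
        double sij = sin_th[i] * cj - cos_th[i] * sj;
        double cij = cos_th[i] * cj + sin_th[i] * sj;
        double dk = -eps2 * (kcol[i] + sij * cb2 + cij * sb2);
        if (sparse) dk *= adj[i + n * j];
        kcol[i] += dt * dk;
      }
    }

    // phase update (Euler-Maruyama), wrap to [0, 2*pi)
    for (int i = 0; i < n; ++i) {
      double nt = th[i] + dt * vel[i];
      if (noise_amp > 0.0) nt += noise_amp * norm_rand();
      nt -= TWOPI * std::floor(nt / TWOPI);
      th[i] = nt;
      if (!std::isfinite(nt))
        stop("non-finite phase at step %d", step + 1);
    }
  }

  NumericVector theta_out(n), vel_out(n);
  NumericMatrix k_out(n, n);
  for (int i = 0; i < n; ++i) { theta_out[i] = th[i]; vel_out[i] = vel[i]; }
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) k_out(i, j) = k[i + n * j];

  return List::create(
    _["R"] = R_series,
    _["R2"] = R2_series,
    _["theta_full"] = theta_full,
    _["vel_full"] = vel_full,
    _["k_frames"] = k_frames,
    _["frame_steps"] = frame_steps,
    _["theta_final"] = theta_out,
    _["k_final"] = k_out,
    _["vel_final"] = vel_out);
}

// Boundary-crossing tracker over a full-resolution phase record.
//
// theta is n x (S + 1), one column per step. The reference direction is the
// unwrapped psi2/2 (half the angle of the second circular moment). Each
// oscillator carries a continuous displacement du from the reference and an
// integer anchor a (multiples of pi): a crossing fires when du - a*pi
// reaches +-(pi - boundary_tol) (the oscillator has covered a full pi from
// its cluster centre up to the numerical arrival tolerance), after which
// the anchor moves to the boundary just reached. The tolerance is needed
// because the anti-podal point is itself the attracting destination of a
// switch: the exact distance pi is only reached asymptotically, at
// round-off-scale speeds, so an exact-pi trigger fires thousands of steps
// after the physical arrival.
//
// Returns the reference series, initial anchors, and the flat crossing
// table (1-based oscillator id, 1-based column index, anchor after).
// [[Rcpp::export]]
List detect_crossings_cpp(NumericMatrix theta, double boundary_tol) {
  const int n = theta.nrow();
  const R_xlen_t s1 = theta.ncol();
  const double TWOPI = 2.0 * M_PI;

  NumericVector ref(s1);
  // unwrapped psi2 / 2
  double prev_psi2 = 0.0, acc_psi2 = 0.0;
  for (R_xlen_t t = 0; t < s1; ++t) {
    double s2r = 0.0, s2i = 0.0;
    const double* col = &theta(0, t);
    for (int i = 0; i < n; ++i) {
      double s = std::sin(col[i]), c = std::cos(col[i]);
      s2r += c * c - s * s;
      s2i += 2.0 * s * c;
    }
    double psi2 = std::atan2(s2i, s2r);
    if (t == 0) {
      acc_psi2 = psi2;
    } else {
      double d = psi2 - prev_psi2;
      d -= TWOPI * std::floor((d + M_PI) / TWOPI); // wrap to (-pi, pi]
      acc_psi2 += d;
    }
    prev_psi2 = psi2;
    ref[t] = acc_psi2 / 2.0;
  }

  IntegerVector anchor0(n);
  std::vector<double> du(n), dprev(n);
  std::vector<int> anchor(n);
  for (int i = 0; i < n; ++i) {
    double d0 = theta(i, 0) - ref[0];
    du[i] = d0;
    dprev[i] = d0;
    int a0 = (int)std::lround(d0 / M_PI);
    anchor0[i] = a0;
    anchor[i] = a0;
  }

  std::vector<int> cross_id, cross_row, cross_anchor;
  for (R_xlen_t t = 1; t < s1; ++t) {
    const double* col = &theta(0, t);
    const double r = ref[t];
    for (int i = 0; i < n; ++i) {
      double d = col[i] - r;
      double delta = d - dprev[i];
      delta -= TWOPI * std::floor((delta + M_PI) / TWOPI);
      dprev[i] = d;
      du[i] += delta;
      const double bnd = M_PI - boundary_tol;
      double rel = du[i] - anchor[i] * M_PI;
      while (rel >= bnd || rel <= -bnd) {
        anchor[i] += (rel > 0) ? 1 : -1;
        rel = du[i] - anchor[i] * M_PI;
        cross_id.push_back(i + 1);
        cross_row.push_back(t + 1);
        cross_anchor.push_back(anchor[i]);
      }
    }
  }

  return List::create(
    _["ref"] = ref,
    _["anchor0"] = anchor0,
    _["id"] = IntegerVector(cross_id.begin(), cross_id.end()),
    _["row"] = IntegerVector(cross_row.begin(), cross_row.end()),
    _["anchor_after"] = IntegerVector(cross_anchor.begin(), cross_anchor.end()));
}
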