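# Overdamped active elastic filament with anisotropic local drag, driven by
# two-harmonic traveling-wave bending torques; tethered-pivot and
# free-swimming modes.
#
# Discretisation: N rigid segments of length h = L/N with tangent angles
# theta_i as generalised coordinates (inextensibility is exact by
# construction).  The overdamped dynamics Gamma(q) dq/dt = -dE/dq + Q_active
# uses the resistive-force-theory friction matrix assembled from per-segment
# anisotropic drag; bending elasticity is linear in theta and integrated
# semi-implicitly, activity and the configuration-dependent friction
# explicitly.  Active torques act as equal-and-opposite couples across each
# interior joint, so the filament carries no net active force or torque.

#' Two-harmonic active torque specification
#'
#' Traveling-wave bending torque
#' `T(s,t) = T0 + T1 sin(ks - w0 t) + T2 sin(ks - 2 w0 t + psi)`
#' with constant amplitudes along the arclength.  `psi` is the phase shift
#' of the second-harmonic torque; it generally differs from the curvature
#' phase `phi` that emerges from the dynamics.
#'
#' @param T1 fundamental torque amplitude (nN um), > 0 when active.
#' @param T_star relative second-harmonic amplitude `T2/T1`.
#' @param psi second-harmonic torque phase (rad), wrapped to (-pi, pi].
#' @param f0 fundamental frequency (Hz); `omega0 = 2*pi*f0`.
#' @param lambda drive wavelength (um); `k = 2*pi/lambda`.
#' @param T0 static torque offset (nN um); a nonzero offset with `T_star =
#'   0` probes the spontaneous second harmonic generated by geometric
#'   nonlinearity.
#' @return object of class `torque_spec`.
#' @export
#' @examples
#' torque_spec()  # the reference tethered-cell drive
torque_spec <- function(T1 = 0.65, T_star = 0.15, psi = 2.26, f0 = 30,
                        lambda = 0.65 * 41, T0 = 0) {
  stopifnot(T1 >= 0, lambda > 0, f0 > 0)
  structure(list(T0 = T0, T1 = T1, T2 = T_star * T1, T_star = T_star,
                 psi = wrap_angle(psi), f0 = f0, omega0 = 2 * pi * f0,
                 lambda = lambda, k = 2 * pi / lambda),
            class = "torque_spec")
}

#' Active torque field of a drive
#'
#' Closed-form evaluation of the two-harmonic torque wave (nN um).
#'
#' @param drive a [torque_spec()].
#' @param s arclength (um), vector allowed.
#' @param t time (s), vector allowed (outer combination is returned when
#'   both have length > 1).
#' @param psi overrides the drive's phase (used for phase schedules).
#' @return torque values; matrix `length(s) x length(t)` when both are
#'   vectors, otherwise a vector.
#' @export
active_torque <- function(drive, s, t, psi = drive$psi) {
  f <- function(s, t) {
    drive$T0 + drive$T1 * sin(drive$k * s - drive$omega0 * t) +
      drive$T2 * sin(drive$k * s - 2 * drive$omega0 * t + psi)
  }
  if (length(s) > 1L && length(t) > 1L) outer(s, t, f) else f(s, t)
}

#' Mechanical model of the discrete filament
#'
#' Geometry, elasticity, drag and head boundary condition of the simulated
#' flagellum.  The default head drag is that of a 2.5 um-radius sphere in
#' the recording medium (viscosity 0.7 fN s / um^2 = 0.7 mPa s):
#' rotational `8 pi eta a^3`, translational `6 pi eta a`.
#'
#' @param L filament length (um).
#' @param N number of segments (>= 20; segment length `L/N` must not exceed
#'   1 um).
#' @param kappa bending rigidity (nN um^2).
#' @param drag a [drag_model()].
#' @param head `"tethered_pivot"` (proximal end pinned, rotation loaded by
#'   the head rotational drag) or `"free"`.
#' @param head_rot_drag head rotational drag (fN s um).
#' @param head_trans_drag head translational drag (fN s / um), free mode
#'   only.
#' @param dt integration time step (s); must resolve the beat
#'   (`dt <= 1/(200 f0)` is checked at simulation time).
#' @return object of class `filament_model`.
#' @export
filament_model <- function(L = 41, N = 50, kappa = 1.9, drag = drag_model(),
                           head = c("tethered_pivot", "free"),
                           head_rot_drag = 8 * pi * 0.7 * 2.5^3,
                           head_trans_drag = 6 * pi * 0.7 * 2.5,
                           dt = 1e-5) {
  head <- match.arg(head)
  stopifnot(N >= 20, L > 0, kappa > 0, dt > 0)
  if (L / N > 1) stop("segment length L/N exceeds 1 um; increase N")
  structure(list(L = L, N = as.integer(N), h = L / N, kappa = kappa,
                 drag = drag, head = head, head_rot_drag = head_rot_drag,
                 head_trans_drag = head_trans_drag, dt = dt),
            class = "filament_model")
}

# Fixed assembly pieces for a given N: the midpoint-Jacobian weight matrix
# Cmat (lower-triangular, 1 below the diagonal, 1/2 on it), its Gram matrix,
# and the bending difference matrix D ((N-1) x N).
filament_matrices <- function(N) {
  Cmat <- matrix(0, N, N)
  Cmat[lower.tri(Cmat)] <- 1
  diag(Cmat) <- 0.5
  D <- diag(-1, N - 1, N)
  D[cbind(seq_len(N - 1), seq(2, N))] <- 1
  list(Cmat = Cmat, G = crossprod(Cmat), D = D, K0 = crossprod(D))
}

#' Simulate the driven filament
#'
#' Integrates the overdamped dynamics for `duration` seconds and records the
#' state every `out_dt`.  Energy ledgers (generated, dissipated in the
#' fluid, dissipated by the head drag, elastic, and the scheme's numerical
#' dissipation) are accumulated exactly per time step, so the discrete
#' power balance `E_g = E_d + delta E_el + E_num` holds to rounding.
#' Period-averaged power profiles are accumulated over whole fundamental
#' periods after `burnin` (rounded to whole periods).
#'
#' @param model a [filament_model()].
#' @param drive a [torque_spec()].
#' @param duration simulated time (s); at least 10 beat periods for steady-
#'   state measurements.
#' @param out_dt output sampling interval (s).
#' @param burnin time (s) excluded from the power-profile accumulation;
#'   default half the duration.
#' @param psi_fun optional function of time overriding the drive phase
#'   (phase steering); `NULL` keeps `drive$psi`.
#' @param ramp_periods the drive amplitude is ramped linearly from zero over
#'   this many fundamental periods to avoid an abrupt start-up transient at
#'   the weakly damped tip.
#' @param theta0 initial tangent angles (rad); default straight along x.
#' @return object of class `filament_sim`: `t` (output times), `theta`
#'   (N x frames), `base` (2 x frames base position), `energy` (data.frame
#'   of cumulative energies, nN um), `Pd_seg`, `Pg_joint` (period-averaged
#'   power per unit length, nN/s per um), `s_mid`, `s_joint`, `model`,
#'   `drive`, plus the realised profile window.
#' @export
simulate_filament <- function(model, drive, duration = 0.5,
                              out_dt = 1 / 500, burnin = duration / 2,
                              psi_fun = NULL, theta0 = NULL,
                              ramp_periods = 2) {
  N <- model$N; h <- model$h
  dt <- model$dt
  if (dt > 1 / (200 * drive$f0)) {
    stop("time step too coarse for the drive frequency: need dt <= 1/(200 f0)")
  }
  mats <- filament_matrices(N)
  kap <- model$kappa * 1e6                 # nN um^2 -> fN um^2
  K <- (kap / h) * mats$K0
  # theta-method weight for the implicit bending term: slightly above 1/2
  # damps stiff-mode ringing while keeping the scheme's numerical
  # dissipation (alpha - 1/2) dt^2 qdot' K qdot far below the physical one
  alpha_th <- 0.52
  xi_par <- model$drag$xi_par; dxi <- model$drag$xi_perp - xi_par
  free <- model$head == "free"
  s_joint <- h * seq_len(N - 1)
  Tper <- 1 / drive$f0
  n_steps <- ceiling(duration / dt)
  stride <- max(1L, round(out_dt / dt))
  n_out <- floor(n_steps / stride) + 1L
  theta <- if (is.null(theta0)) rep(0, N) else rep_len(theta0, N)
  base <- c(0, 0)
  # output storage
  TH <- matrix(NA_real_, N, n_out)
  BASE <- matrix(NA_real_, 2, n_out)
  EN <- matrix(0, 6, n_out)  # Eg, Ed, Ehead, Eel, Enum, t
  TH[, 1] <- theta; BASE[, 1] <- base
  # profile accumulation window: whole periods after burnin
  prof_start <- ceiling(burnin / Tper) * Tper
  n_prof_periods <- floor((duration - prof_start) / Tper)
  prof_end <- prof_start + n_prof_periods * Tper
  if (n_prof_periods < 1) {
    prof_start <- Inf; prof_end <- -Inf
  }
  Pd_acc <- numeric(N); Pg_acc <- numeric(N - 1); head_acc <- 0
  prof_steps <- 0L
  Eg <- Ed <- Ehead <- Enum <- 0
  Eel <- kap / (2 * h) * sum((mats$D %*% theta)^2)
  T1f <- drive$T1 * 1e6; T2f <- drive$T2 * 1e6; T0f <- drive$T0 * 1e6
  k <- drive$k; w0 <- drive$omega0
  out_i <- 1L
  for (step in seq_len(n_steps)) {
    t_now <- (step - 1) * dt
    cx <- cos(theta); sx <- sin(theta)
    cosdiff <- outer(cx, cx) + outer(sx, sx)   # cos(theta_i - theta_j)
    Jn <- h * mats$Cmat * cosdiff              # n_i . dm_i/dtheta_j
    Gam <- xi_par * h^3 * (mats$G * cosdiff) + dxi * h * crossprod(Jn)
    psi_now <- if (is.null(psi_fun)) drive$psi else psi_fun(t_now)
    Tj <- T0f + T1f * sin(k * s_joint - w0 * t_now) +
      T2f * sin(k * s_joint - 2 * w0 * t_now + psi_now)
    if (ramp_periods > 0) Tj <- Tj * min(1, t_now / (ramp_periods * Tper))
    Q <- c(0, Tj) - c(Tj, 0)
    if (!free) {
      Gam[1, 1] <- Gam[1, 1] + model$head_rot_drag
      A <- Gam + (alpha_th * dt) * K
      rhs <- Gam %*% theta - ((1 - alpha_th) * dt) * (K %*% theta) + dt * Q
      theta_new <- solve(A, rhs)
      qdot <- (theta_new - theta) / dt
      base_new <- base
      vbase <- c(0, 0)
    } else {
      # free mode: generalised coordinates (x0, y0, theta)
      nvec_x <- -sx; nvec_y <- cx
      colC <- colSums(mats$Cmat)
      colJx <- -h * sx * colC                    # sum_i dm_i,x/dtheta_j
      colJy <- h * cx * colC
      # cross blocks Gamma_{(x0,y0), theta_j}
      gx <- xi_par * h * colJx + dxi * h * colSums(Jn * nvec_x)
      gy <- xi_par * h * colJy + dxi * h * colSums(Jn * nvec_y)
      Sxx <- xi_par * h * N + dxi * h * sum(nvec_x^2) + model$head_trans_drag
      Syy <- xi_par * h * N + dxi * h * sum(nvec_y^2) + model$head_trans_drag
      Sxy <- dxi * h * sum(nvec_x * nvec_y)
      Gam[1, 1] <- Gam[1, 1] + model$head_rot_drag
      Gfull <- rbind(cbind(matrix(c(Sxx, Sxy, Sxy, Syy), 2, 2),
                           rbind(gx, gy)),
                     cbind(cbind(gx, gy), Gam))
      Kfull <- matrix(0, N + 2, N + 2)
      Kfull[3:(N + 2), 3:(N + 2)] <- K
      q <- c(base, theta)
      A <- Gfull + (alpha_th * dt) * Kfull
      rhs <- Gfull %*% q - ((1 - alpha_th) * dt) * (Kfull %*% q) +
        dt * c(0, 0, Q)
      q_new <- solve(A, rhs)
      base_new <- q_new[1:2]
      theta_new <- q_new[3:(N + 2)]
      qdot <- (theta_new - theta) / dt
      vbase <- (base_new - base) / dt
    }
    if (any(!is.finite(theta_new)) || max(abs(theta_new - theta)) > 1) {
      stop("simulation unstable at t = ", signif(t_now, 4),
           " s: tangent-angle step exceeded 1 rad; reduce dt or the drive")
    }
    # exact discrete energy ledger (fN um -> store, convert to nN um at end)
    Pg_step <- sum(Q * qdot)
    if (!free) {
      Pdrag_step <- sum(qdot * (Gam %*% qdot))
    } else {
      vq <- c(vbase, qdot)
      Pdrag_step <- sum(vq * (Gfull %*% vq))
    }
    Phead <- model$head_rot_drag * qdot[1]^2 +
      if (free) model$head_trans_drag * sum(vbase^2) else 0
    Enum_step <- (alpha_th - 0.5) * dt^2 * sum(qdot * (K %*% qdot))
    Eg <- Eg + dt * Pg_step
    Ed <- Ed + dt * (Pdrag_step - Phead)
    Ehead <- Ehead + dt * Phead
    Enum <- Enum + Enum_step
    # per-arclength power profiles inside the accumulation window
    if (t_now >= prof_start && t_now < prof_end) {
      vmx <- -h * (mats$Cmat %*% (sx * qdot)) + vbase[1]
      vmy <- h * (mats$Cmat %*% (cx * qdot)) + vbase[2]
      vt <- vmx * cx + vmy * sx
      vn <- -vmx * sx + vmy * cx
      Pd_acc <- Pd_acc + (xi_par * vt^2 + model$drag$xi_perp * vn^2)
      Pg_acc <- Pg_acc + Tj * diff(qdot) / h
      head_acc <- head_acc + Phead
      prof_steps <- prof_steps + 1L
    }
    theta <- as.numeric(theta_new); base <- base_new
    if (step %% stride == 0L && out_i < n_out) {
      out_i <- out_i + 1L
      TH[, out_i] <- theta
      BASE[, out_i] <- base
      Eel_now <- kap / (2 * h) * sum((mats$D %*% theta)^2)
      EN[, out_i] <- c(Eg, Ed, Ehead, Eel_now - Eel, Enum, step * dt)
    }
  }
  keep <- seq_len(out_i)
  energy <- data.frame(t = EN[6, keep], E_g = EN[1, keep] / 1e6,
                       E_d = EN[2, keep] / 1e6, E_head = EN[3, keep] / 1e6,
                       dE_el = EN[4, keep] / 1e6, E_num = EN[5, keep] / 1e6)
  energy$t[1] <- 0
  structure(list(
    t = energy$t, theta = TH[, keep, drop = FALSE],
    base = BASE[, keep, drop = FALSE], energy = energy,
    Pd_seg = if (prof_steps > 0) Pd_acc / prof_steps / 1e6 else rep(NA_real_, N),
    Pg_joint = if (prof_steps > 0) Pg_acc / prof_steps / 1e6 else rep(NA_real_, N - 1),
    P_head = if (prof_steps > 0) head_acc / prof_steps / 1e6 else NA_real_,
    s_mid = h * (seq_len(N) - 0.5), s_joint = s_joint,
    profile_window = c(prof_start, prof_end), n_prof_periods = n_prof_periods,
    model = model, drive = drive
  ), class = "filament_sim")
}

#' @export
print.filament_sim <- function(x, ...) {
  cat(sprintf("Filament simulation: N = %d, L = %g um, %s head, %.3g s\n",
              x$model$N, x$model$L, x$model$head, max(x$t)))
  cat(sprintf("  drive: T1 = %g nN um, T* = %g, psi = %.3f, f0 = %g Hz, lambda = %g um\n",
              x$drive$T1, x$drive$T_star, x$drive$psi, x$drive$f0,
              x$drive$lambda))
  if (x$model$head != "free") {
    om <- tryCatch(measure_rotation(x), error = function(e) NULL,
                   warning = function(w) suppressWarnings(measure_rotation(x)))
    if (!is.null(om)) {
      cat(sprintf("  steady rotation Omega = %.4g +/- %.2g rev/s\n",
                  om$Omega, om$sd))
    }
  }
  invisible(x)
}

# Joint positions (2 x (N+1) x frames is avoided; returns list of x, y
# matrices (N+1) x frames) of a simulation.
sim_positions <- function(sim) {
  h <- sim$model$h
  cx <- cos(sim$theta); sx <- sin(sim$theta)
  X <- rbind(0, h * apply(cx, 2, cumsum))
  Y <- rbind(0, h * apply(sx, 2, cumsum))
  X <- sweep(X, 2, sim$base[1, ], `+`)
  Y <- sweep(Y, 2, sim$base[2, ], `+`)
  list(x = X, y = Y)
}

#' Emergent curvature field of a simulation
#'
#' Discrete curvature at the interior joints,
#' `C_i(t) = (theta_{i+1} - theta_i)/h`, as a [curvature_field] ready for
#' the kinematics/modes/harmonics pipeline.
#'
#' @param sim a `filament_sim`.
#' @return a [curvature_field] on `s_joint`.
#' @export
sim_curvature <- function(sim) {
  dC <- diff(sim$theta) / sim$model$h
  curvature_field(dC, sim$s_joint, sim$t)
}

#' Steady rotation velocity of a tethered simulation
#'
#' Period-averaged rotation rate of the body frame (the proximal tangent
#' angle), mean and SD over the whole fundamental periods in the second half
#' of the record.
#'
#' @param sim a `filament_sim` (tethered mode).
#' @param min_periods minimum number of whole periods required.
#' @return list with `Omega` (rev/s), `sd`, `per_period` (rev/s per period).
#'   Warns when a linear trend across periods exceeds 3 SD (non-stationary).
#' @export
measure_rotation <- function(sim, min_periods = 5) {
  Tper <- 1 / sim$drive$f0
  t <- sim$t
  alpha <- unwrap_angle(sim$theta[1, ])
  t0 <- max(t) / 2
  starts <- seq(ceiling(t0 / Tper) * Tper, max(t) - Tper, by = Tper)
  if (length(starts) < min_periods) {
    stop("fewer than ", min_periods, " steady periods available")
  }
  a_at <- stats::spline(t, alpha,
                        xout = c(starts, starts[length(starts)] + Tper))$y
  per <- diff(a_at) / Tper / (2 * pi)
  if (length(per) >= 3) {
    tr <- stats::coef(stats::lm(per ~ seq_along(per)))[2] * length(per)
    if (is.finite(tr) && stats::sd(per) > 0 && abs(tr) > 3 * stats::sd(per)) {
      warning("rotation velocity non-stationary across periods")
    }
  }
  list(Omega = mean(per), sd = stats::sd(per), per_period = per)
}

#' Parameter sweep of the tethered simulation
#'
#' Re-simulates over a grid of one drive parameter and reports the steady
#' rotation velocity, the mean curvature, and the emergent harmonic content
#' (C1, C2, phi at the mid-flagellum probe) of each run.  Individual
#' failures are recorded and the sweep continues.
#'
#' @param model a [filament_model()].
#' @param drive a [torque_spec()] giving the non-swept parameters.
#' @param parameter one of `"T_star"`, `"psi"`, `"lambda"`.
#' @param grid values of the swept parameter.
#' @param duration,out_dt,burnin passed to [simulate_filament()].
#' @param harmonics_W spectrogram window (frames at `1/out_dt`).
#' @return data.frame with columns `value`, `Omega`, `Omega_sd`, `C_mean`,
#'   `C1`, `C2`, `phi`, `ok`.
#' @export
sweep_drive <- function(model, drive, parameter = c("T_star", "psi", "lambda"),
                        grid, duration = 0.5, out_dt = 1 / 500,
                        burnin = duration / 2, harmonics_W = 100) {
  parameter <- match.arg(parameter)
  rows <- lapply(grid, function(v) {
    d <- drive
    if (parameter == "T_star") {
      d <- torque_spec(T1 = drive$T1, T_star = v, psi = drive$psi,
                       f0 = drive$f0, lambda = drive$lambda, T0 = drive$T0)
    } else if (parameter == "psi") {
      d <- torque_spec(T1 = drive$T1, T_star = drive$T_star, psi = v,
                       f0 = drive$f0, lambda = drive$lambda, T0 = drive$T0)
    } else {
      d <- torque_spec(T1 = drive$T1, T_star = drive$T_star, psi = drive$psi,
                       f0 = drive$f0, lambda = v, T0 = drive$T0)
    }
    out <- data.frame(value = v, Omega = NA_real_, Omega_sd = NA_real_,
                      C_mean = NA_real_, C1 = NA_real_, C2 = NA_real_,
                      phi = NA_real_, ok = FALSE)
    tryCatch({
      sim <- simulate_filament(model, d, duration = duration,
                               out_dt = out_dt, burnin = burnin)
      om <- suppressWarnings(measure_rotation(sim))
      cf <- sim_curvature(sim)
      tail_idx <- cf$t >= burnin
      out$C_mean <- mean(cf$C[, tail_idx])
      W_use <- min(harmonics_W, sum(tail_idx))
      tr <- spectrogram_harmonics(
        cf$C[which.min(abs(cf$s - model$L / 2)), tail_idx],
        frame_rate = 1 / out_dt, W = W_use,
        step = max(8, W_use %/% 8),
        band = c(0.5, 1.6) * d$f0, t0 = cf$t[tail_idx][1])
      ok <- is.finite(tr$C1)
      out$Omega <- om$Omega; out$Omega_sd <- om$sd
      out$C1 <- mean(tr$C1[ok]); out$C2 <- mean(tr$C2[ok])
      out$phi <- Arg(mean(exp(1i * tr$phi[ok])))
      out$ok <- TRUE
      out
    }, error = function(e) {
      out$ok <- FALSE
      attr(out, "error") <- conditionMessage(e)
      out
    })
  })
  do.call(rbind, rows)
}

#' Free-swimming trajectory under a phase schedule
#'
#' Simulates the free filament while the second-harmonic torque phase psi
#' follows `psi_fun(t)`, and summarises the swimming path: the beat-averaged
#' head trajectory and its signed path curvature.
#'
#' @param model a [filament_model()] (head mode is forced to `"free"`).
#' @param drive a [torque_spec()].
#' @param psi_fun function of time (s) returning psi (rad); `NULL` keeps the
#'   drive's constant psi.
#' @param duration simulated time (s).
#' @param ... passed to [simulate_filament()].
#' @return list with `sim`, `path` (data.frame `t`, `x`, `y`: beat-averaged
#'   head position) and `path_curvature` (data.frame `t`, `kappa_path`
#'   (1/um), `psi`).
#' @export
free_swim <- function(model, drive, psi_fun = NULL, duration = 1, ...) {
  model$head <- "free"
  sim <- simulate_filament(model, drive, duration = duration,
                           psi_fun = psi_fun, ...)
  Tper <- 1 / drive$f0
  dt <- stats::median(diff(sim$t))
  xs <- gaussian_smooth(sim$base[1, ], dt, Tper / 2)
  ys <- gaussian_smooth(sim$base[2, ], dt, Tper / 2)
  # sample once per period for the path summary
  idx <- seq(1, length(sim$t), by = max(1L, round(Tper / dt)))
  px <- xs[idx]; py <- ys[idx]; pt <- sim$t[idx]
  heading <- atan2(diff(py), diff(px))
  seg <- sqrt(diff(px)^2 + diff(py)^2)
  kap <- wrap_angle(diff(heading)) / ((seg[-1] + seg[-length(seg)]) / 2)
  tk <- pt[2:(length(pt) - 1)]
  psi_t <- if (is.null(psi_fun)) rep(drive$psi, length(tk)) else psi_fun(tk)
  list(sim = sim,
       path = data.frame(t = pt, x = px, y = py),
       path_curvature = data.frame(t = tk, kappa_path = kap, psi = psi_t))
}

#' Period-averaged power profiles
#'
#' Dissipated power per unit length `P_d(s) = <xi_perp v_perp^2 + xi_par
#' v_par^2>` at segment midpoints and generated power per unit length
#' `P_g(s) = <T(s,t) dC/dt>` at the joints, averaged over the whole
#' fundamental periods of the simulation's profile window.  Optionally
#' restricted to an arclength window for comparison with tracked recordings.
#'
#' @param sim a `filament_sim` run with a valid profile window.
#' @param s_window optional arclength window (um), e.g. `c(7, 35)`.
#' @return list with `s_d`, `P_d`, `s_g`, `P_g` (nN/s per um), `P_head`
#'   (nN um/s), and the integrals `int_P_d`, `int_P_g` (nN um/s).
#' @export
power_profiles <- function(sim, s_window = NULL) {
  if (sim$n_prof_periods < 1 || any(!is.finite(sim$Pd_seg))) {
    stop("simulation has no whole-period profile window; rerun with a ",
         "longer duration or earlier burnin")
  }
  s_d <- sim$s_mid; P_d <- sim$Pd_seg
  s_g <- sim$s_joint; P_g <- sim$Pg_joint
  int_P_d <- sum(P_d) * sim$model$h
  int_P_g <- sum(P_g) * sim$model$h
  if (!is.null(s_window)) {
    kd <- s_d >= s_window[1] & s_d <= s_window[2]
    kg <- s_g >= s_window[1] & s_g <= s_window[2]
    s_d <- s_d[kd]; P_d <- P_d[kd]
    s_g <- s_g[kg]; P_g <- P_g[kg]
  }
  list(s_d = s_d, P_d = P_d, s_g = s_g, P_g = P_g, P_head = sim$P_head,
       int_P_d = int_P_d, int_P_g = int_P_g)
}

#' Spontaneous second harmonic from geometric nonlinearity
#'
#' Runs the simulator with a purely fundamental torque superimposed on a
#' static torque offset (no second-harmonic drive) and measures the
#' emergent second-harmonic content of the curvature with the spectrogram.
#' Geometric nonlinearity alone generates a second harmonic whose relative
#' amplitude grows with the drive.
#'
#' @param model a [filament_model()].
#' @param drive a [torque_spec()] with `T_star = 0`; `T0` may be nonzero.
#' @param duration simulated time (s).
#' @param s0 probe arclength (um); default mid-flagellum.
#' @param out_dt output sampling (s).
#' @return list with `trace` (a `harmonic_trace`), `C2_over_C1` (mean),
#'   `phi` (circular mean), `sim`.
#' @export
emergent_second_harmonic <- function(model, drive, duration = 0.6,
                                     s0 = model$L / 2, out_dt = 1 / 500) {
  if (drive$T_star != 0) stop("use T_star = 0 to probe the emergent harmonic")
  sim <- simulate_filament(model, drive, duration = duration, out_dt = out_dt)
  cf <- sim_curvature(sim)
  tail_idx <- cf$t >= duration / 3
  # window of (nearly) whole beat periods: minimises rectangular-window
  # leakage of the strong fundamental into the 2 f0 bin
  W_use <- max(64, round(9 * (1 / out_dt) / drive$f0))
  tr <- spectrogram_harmonics(cf$C[which.min(abs(cf$s - s0)), tail_idx],
                              frame_rate = 1 / out_dt, W = W_use,
                              step = max(8, W_use %/% 8),
                              band = c(0.5, 1.6) * drive$f0,
                              t0 = cf$t[tail_idx][1])
  ok <- is.finite(tr$C1) & tr$C1 > 0
  list(trace = tr,
       C2_over_C1 = mean(tr$C2[ok] / tr$C1[ok]),
       phi = Arg(mean(exp(1i * tr$phi[ok]))),
       sim = sim)
}
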