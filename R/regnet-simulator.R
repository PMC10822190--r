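#' Build the 10-node regulatory-network model
#'
#' A Michaelis-Menten/Hill regulatory network with a known tipping point,
#' used to generate staged validation data. Three mutually activating core
#' nodes carry the bifurcation: their degradation rate is `d_core - p`, so
#' increasing the control parameter `p` weakens degradation until the low
#' expression state is lost in a fold bifurcation. Seven background nodes
#' receive mixed activation/inhibition (two driven by the core, the rest in
#' an acyclic chain) and have constant degradation. The drift of node i is
#'
#' `F_i(z) = sum_{j act i} beta * z_j^h / (S^h + z_j^h)
#'         + sum_{j inh i} beta * S^h / (S^h + z_j^h) + b_i - d_i(p) * z_i`.
#'
#' At construction, `d_core` is calibrated so the leading Jacobian
#' eigenvalue at the low-state equilibrium crosses 0 exactly at `p = 0`
#' (`lambda_max(p) < 0` for `p < 0`), and this eigenvalue-crossing
#' invariant is verified numerically on a grid; calibration failure is an
#' error.
#'
#' @param n_core number of core nodes (default 3).
#' @param n_background number of background nodes (default 7).
#' @param beta regulation strength (default 1).
#' @param S half-saturation constant (default 1).
#' @param h Hill coefficient (default 2).
#' @param b basal production rate (default 0.1).
#' @param d_background background degradation rate (default 1).
#' @param noise_sd default Langevin noise SD (default 0.05).
#' @param check_grid p values at which the eigenvalue invariant is checked.
#' @return object of class `regnet_model`.
#' @export
build_regnet_model <- function(n_core = 3L, n_background = 7L, beta = 1,
                               S = 1, h = 2, b = 0.1, d_background = 1,
                               noise_sd = 0.05,
                               check_grid = seq(-0.5, -0.05, by = 0.05)) {
  stopifnot(n_core >= 2L, n_background >= 0L, beta > 0, S > 0, h > 0,
            b >= 0, d_background > 0)
  n <- n_core + n_background
  core <- seq_len(n_core)
  act <- matrix(0, n, n)  # act[i, j] = 1: j activates i
  inh <- matrix(0, n, n)
  # mutually activating core (no self-activation)
  act[core, core] <- 1
  diag(act)[core] <- 0
  # background wiring: two nodes driven by the core, the rest an acyclic
  # mixed chain so the Jacobian stays block-triangular
  if (n_background >= 1L) act[n_core + 1L, 1L] <- 1
  if (n_background >= 2L) inh[n_core + 2L, 2L] <- 1
  for (k in seq_len(max(n_background - 2L, 0L))) {
    i <- n_core + 2L + k
    if (k %% 2L == 1L) act[i, i - 1L] <- 1 else inh[i, i - 1L] <- 1
  }
  model <- list(n = n, core = core, act = act, inh = inh, beta = beta,
                S = S, h = h, b = rep(b, n), d_background = d_background,
                noise_sd = noise_sd)
  # calibrate core degradation so the fold sits at p = 0: at the fold the
  # symmetric low-state equilibrium satisfies drift = 0 and d(drift)/dz = 0
  # for the scalar core equation (n_core - 1) * beta * H(z) + b - d * z
  kact <- n_core - 1L
  hill <- function(z) z^h / (S^h + z^h)
  dhill <- function(z) h * S^h * z^(h - 1L) / (S^h + z^h)^2
  fold <- function(z) kact * beta * hill(z) + b - kact * beta * dhill(z) * z
  zs <- seq(1e-4, S * 2, length.out = 4000L)
  vals <- fold(zs)
  sgn <- which(diff(sign(vals)) != 0)
  if (length(sgn) == 0L) {
    stop("no fold point found; core parameterization does not bifurcate")
  }
  z_fold <- stats::uniroot(fold, c(zs[sgn[1L]], zs[sgn[1L] + 1L]),
                           tol = 1e-12)$root
  model$d_core <- kact * beta * dhill(z_fold)
  model$z_fold <- z_fold
  class(model) <- "regnet_model"
  # verify the eigenvalue-crossing invariant on the requested grid
  lam <- vapply(check_grid, function(p) regnet_lambda_max(model, p),
                numeric(1L))
  if (any(check_grid < -0.05 & lam >= 0)) {
    stop("bad parameterization: lambda_max >= 0 at some p < -0.05")
  }
  lam0 <- regnet_lambda_max(model, 0)
  if (abs(lam0) > 1e-3) {
    stop("bad parameterization: lambda_max(0) = ", signif(lam0, 3),
         " (should be 0 within 1e-3)")
  }
  model$lambda_check <- data.frame(p = c(check_grid, 0),
                                   lambda_max = c(lam, lam0))
  model
}

#' @export
print.regnet_model <- function(x, ...) {
  cat(sprintf(
    "regnet_model: %d nodes (%d-node core), h = %g, beta = %g, S = %g\n",
    x$n, length(x$core), x$h, x$beta, x$S))
  cat(sprintf("  d_core = %.6f (calibrated: fold bifurcation at p = 0, z_fold = %.4f)\n",
              x$d_core, x$z_fold))
  cat(sprintf("  d_background = %g, noise_sd = %g\n",
              x$d_background, x$noise_sd))
  invisible(x)
}

# degradation vector at parameter p (p accelerates only the core)
.regnet_d <- function(model, p) {
  d <- rep(model$d_background, model$n)
  d[model$core] <- model$d_core - p
  d
}

#' Drift of the regulatory network
#'
#' @param model a `regnet_model`.
#' @param z state vector (length n) or matrix (rows = states).
#' @param p bifurcation parameter.
#' @return drift, same shape as `z`.
#' @export
regnet_drift <- function(model, z, p) {
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  H <- zm^model$h / (model$S^model$h + zm^model$h)
  drift <- model$beta * (H %*% t(model$act) + (1 - H) %*% t(model$inh))
  drift <- sweep(drift, 2L, model$b, `+`) -
    sweep(zm, 2L, .regnet_d(model, p), `*`)
  if (is.matrix(z)) drift else drift[1L, ]
}

# analytic Jacobian at state z
.regnet_jacobian <- function(model, z, p) {
  dH <- model$h * model$S^model$h * z^(model$h - 1L) /
    (model$S^model$h + z^model$h)^2
  J <- model$beta * (model$act - model$inh) * rep(dH, each = model$n)
  diag(J) <- diag(J) - .regnet_d(model, p)
  J
}

#' Low-state equilibrium of the network
#'
#' Damped Newton iteration from the origin; converges to the pre-transition
#' (low expression) equilibrium for `p` below the fold.
#'
#' @param model a `regnet_model`.
#' @param p bifurcation parameter.
#' @param z0 optional starting state (default small positive).
#' @param tol convergence tolerance on the drift norm.
#' @param max_iter iteration cap.
#' @return equilibrium state vector.
#' @export
regnet_equilibrium <- function(model, p, z0 = NULL, tol = 1e-12,
                               max_iter = 200L) {
  z <- z0 %||% rep(0.01, model$n)
  for (it in seq_len(max_iter)) {
    f <- regnet_drift(model, z, p)
    if (sqrt(sum(f^2)) < tol) return(z)
    J <- .regnet_jacobian(model, z, p)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) step <- f  # fall back to damped fixed point
    lambda <- 1
    repeat {
      z_new <- pmax(z + lambda * step, 0)
      if (sqrt(sum(regnet_drift(model, z_new, p)^2)) < sqrt(sum(f^2)) ||
          lambda < 1e-6) break
      lambda <- lambda / 2
    }
    z <- pmax(z + lambda * step, 0)
  }
  if (sqrt(sum(regnet_drift(model, z, p)^2)) > 1e-6) {
    stop("equilibrium iteration failed to converge at p = ", p)
  }
  z
}

#' Leading Jacobian eigenvalue at the low-state equilibrium
#'
#' @param model a `regnet_model`.
#' @param p bifurcation parameter.
#' @return largest real part of the Jacobian spectrum.
#' @export
regnet_lambda_max <- function(model, p) {
  # at and beyond the fold the low equilibrium is the fold point itself
  z <- tryCatch(regnet_equilibrium(model, p),
                error = function(e) NULL)
  if (is.null(z)) {
    z <- rep(0, model$n)
    z[model$core] <- model$z_fold
    z <- regnet_equilibrium(model, max(p, 0), z0 = z, max_iter = 5L) |>
      suppressWarnings()
  }
  J <- .regnet_jacobian(model, z, p)
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' Sample from the stationary linearized (Langevin) distribution
#'
#' For a stable equilibrium (`lambda_max(p) < 0`) the linearized Langevin
#' system has a Gaussian stationary law centred at the equilibrium with
#' covariance `Sigma` solving the Lyapunov equation
#' `J Sigma + Sigma J' + noise_sd^2 I = 0`. Samples are drawn from it and
#' rectified at 0. Near the tipping point the covariance inflates along the
#' critical (core) direction.
#'
#' @param model a `regnet_model`.
#' @param p bifurcation parameter with `lambda_max(p) < 0`.
#' @param n number of samples.
#' @param seed RNG seed (optional; uses the current RNG stream if `NULL`).
#' @param noise_sd noise SD override (default: the model's).
#' @return n x n_nodes sample matrix.
#' @export
stationary_sample <- function(model, p, n, seed = NULL, noise_sd = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd_n <- noise_sd %||% model$noise_sd
  z_star <- tryCatch(regnet_equilibrium(model, p), error = function(e) {
    stop("stationary backend needs a stable low state (lambda_max < 0); ",
         "no equilibrium at p = ", p,
         " -- use the euler backend at/after the tipping point")
  })
  J <- .regnet_jacobian(model, z_star, p)
  lam <- max(Re(eigen(J, only.values = TRUE)$values))
  if (lam >= 0) {
    stop("stationary backend needs lambda_max < 0 (got ", signif(lam, 3),
         "); use the euler backend at/after the tipping point")
  }
  if (sd_n == 0) {
    return(matrix(rep(z_star, each = n), nrow = n,
                  dimnames = list(NULL, .regnet_node_names(model))))
  }
  Sigma <- .solve_lyapunov(J, sd_n^2 * diag(model$n))
  L <- t(chol(Sigma + 1e-14 * diag(model$n)))
  eps <- matrix(stats::rnorm(n * model$n), nrow = model$n)
  samples <- t(z_star + L %*% eps)
  samples[samples < 0] <- 0
  colnames(samples) <- .regnet_node_names(model)
  samples
}

# solve J S + S J' + C = 0 via the Kronecker form
.solve_lyapunov <- function(J, C) {
  n <- nrow(J)
  K <- kronecker(diag(n), J) + kronecker(J, diag(n))
  S <- matrix(solve(K, -as.vector(C)), n, n)
  (S + t(S)) / 2
}

.regnet_node_names <- function(model) {
  sprintf("g%d", seq_len(model$n))
}

#' Sample by Euler-Maruyama integration
#'
#' Integrates `n` independent trajectories of the full nonlinear Langevin
#' system (`dz = F(z) dt + noise_sd dW`, rectified at 0) and records the
#' endpoints after `burn_in` time units. This backend remains valid at and
#' beyond the tipping point, where no stable low equilibrium exists; there
#' the trajectories start from the last stable low state (the fold point).
#'
#' @param model a `regnet_model`.
#' @param p bifurcation parameter.
#' @param n number of trajectories.
#' @param seed RNG seed (optional).
#' @param dt integration step (default 0.02).
#' @param burn_in integration time before the endpoint is taken
#'   (default 40).
#' @param noise_sd noise SD override.
#' @param z_max divergence guard (default 100).
#' @return n x n_nodes endpoint matrix.
#' @export
euler_maruyama_sample <- function(model, p, n, seed = NULL, dt = 0.02,
                                  burn_in = 40, noise_sd = NULL,
                                  z_max = 100) {
  stopifnot(dt > 0, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  sd_n <- noise_sd %||% model$noise_sd
  z0 <- tryCatch(regnet_equilibrium(model, p), error = function(e) NULL)
  if (is.null(z0)) {
    z0 <- model$b / model$d_background
    z0[model$core] <- model$z_fold
  }
  z <- matrix(rep(z0, each = n), nrow = n)
  n_steps <- ceiling(burn_in / dt)
  sqdt <- sqrt(dt)
  for (s in seq_len(n_steps)) {
    z <- z + regnet_drift(model, z, p) * dt
    if (sd_n > 0) {
      z <- z + sd_n * sqdt * matrix(stats::rnorm(n * model$n), nrow = n)
    }
    z[z < 0] <- 0
    if (any(z > z_max)) {
      stop("trajectory divergence (|z| > ", z_max, ") at p = ", p)
    }
  }
  colnames(z) <- .regnet_node_names(model)
  z
}

#' Simulate a staged sweep over the bifurcation parameter
#'
#' Generates one "stage" of `n` samples per grid value of `p` (ascending)
#' and packages the result as a `staged_expression_set` (nodes as genes,
#' one stage per `p`). The default grid is 16 evenly spaced values spanning
#' `[-0.5, 0.25]` with `p = 0` on the grid; the tipping point sits at
#' `p = 0` by model construction.
#'
#' @param model a `regnet_model` (default: [build_regnet_model()]).
#' @param grid ascending p values; must include 0 when it spans the
#'   tipping point (default `(-10:5)/20`).
#' @param n samples per stage (default 50).
#' @param seed RNG seed for the whole sweep (default 1).
#' @param backend `"auto"` (stationary where stable, Euler-Maruyama
#'   otherwise), `"stationary"`, or `"euler"`.
#' @param noise_sd intrinsic (Langevin) noise SD override.
#' @param obs_noise_sd SD of additive Gaussian observation noise applied
#'   to every sampled value (rectified at 0; default 0).
#' @param dt,burn_in Euler-Maruyama settings.
#' @return list with `set` (a `staged_expression_set`), `p_values` (named
#'   by stage label), `samples` (per-stage matrices), `backend_used`,
#'   `seed`.
#' @export
sweep_parameter <- function(model = build_regnet_model(),
                            grid = (-10:5) / 20, n = 50L, seed = 1L,
                            backend = c("auto", "stationary", "euler"),
                            noise_sd = NULL, obs_noise_sd = 0, dt = 0.02,
                            burn_in = 40) {
  backend <- match.arg(backend)
  grid <- sort(grid)
  if (min(grid) < 0 && max(grid) >= 0 && !any(grid == 0)) {
    stop("a grid spanning the tipping point must include p = 0")
  }
  set.seed(seed)
  labels <- sprintf("p=%+.3f", grid)
  lam <- vapply(grid, function(p) {
    tryCatch(regnet_lambda_max(model, p), error = function(e) Inf)
  }, numeric(1L))
  used <- character(length(grid))
  mats <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    use_euler <- switch(backend,
                        euler = TRUE,
                        stationary = FALSE,
                        auto = !(lam[i] < -1e-3))
    if (!use_euler && lam[i] >= 0) {
      stop("stationary backend is invalid at p = ", grid[i],
           " (lambda_max >= 0)")
    }
    mats[[i]] <- if (use_euler) {
      euler_maruyama_sample(model, grid[i], n, noise_sd = noise_sd,
                            dt = dt, burn_in = burn_in)
    } else {
      stationary_sample(model, grid[i], n, noise_sd = noise_sd)
    }
    if (obs_noise_sd > 0) {
      mats[[i]] <- mats[[i]] +
        matrix(stats::rnorm(length(mats[[i]]), sd = obs_noise_sd),
               nrow = nrow(mats[[i]]))
      mats[[i]][mats[[i]] < 0] <- 0
    }
    used[i] <- if (use_euler) "euler" else "stationary"
  }
  names(mats) <- labels
  big <- t(do.call(rbind, mats))
  sample_ids <- unlist(lapply(seq_along(grid), function(i) {
    sprintf("%s_s%02d", labels[i], seq_len(n))
  }))
  colnames(big) <- sample_ids
  map <- stats::setNames(rep(labels, each = n), sample_ids)
  set <- build_staged_set(big, map)
  list(set = set,
       p_values = stats::setNames(grid, labels),
       samples = mats,
       backend_used = stats::setNames(used, labels),
       seed = seed)
}

#' Detection-robustness harness over noise levels
#'
#' For each noise SD, regenerates the default sweep `replicates` times with
#' fresh seeds, runs the full scoring pipeline and records the fraction of
#' replicates in which the detected critical stage is the `p = 0` stage.
#' By default the varied noise is the additive Gaussian observation noise
#' laid over the sampled trajectories (the intrinsic Langevin noise stays
#' at the model's value); `noise_type = "intrinsic"` varies the Langevin
#' noise itself instead.
#'
#' @param model a `regnet_model`.
#' @param noise_levels numeric vector of noise SDs.
#' @param replicates replicates per level.
#' @param seed base seed; replicate r at level l uses
#'   `seed + 1000 * (l - 1) + r`.
#' @param n samples per stage (default 50).
#' @param grid sweep grid (default `(-10:5)/20`).
#' @param quantile network retention quantile (default 0.9).
#' @param noise_type `"observation"` (default) or `"intrinsic"`.
#' @return data.frame with `noise_sd`, `successes`, `replicates`,
#'   `success_fraction`.
#' @export
robustness_harness <- function(model = build_regnet_model(),
                               noise_levels = c(0.01, 0.05, 0.1),
                               replicates = 20L, seed = 1L, n = 50L,
                               grid = (-10:5) / 20, quantile = 0.9,
                               noise_type = c("observation", "intrinsic")) {
  stopifnot(replicates >= 1L)
  replicates <- as.integer(replicates)
  noise_type <- match.arg(noise_type)
  rows <- lapply(seq_along(noise_levels), function(l) {
    succ <- 0L
    for (r in seq_len(replicates)) {
      sw <- sweep_parameter(model, grid = grid, n = n,
                            seed = seed + 1000L * (l - 1L) + r,
                            noise_sd = if (noise_type == "intrinsic")
                              noise_levels[l] else NULL,
                            obs_noise_sd = if (noise_type == "observation")
                              noise_levels[l] else 0)
      res <- score_all_stages(sw$set, quantile = quantile, run_gof = FALSE)
      series <- stats::setNames(vapply(res, `[[`, numeric(1L), "global"),
                                vapply(res, `[[`, character(1L), "stage"))
      det <- detect_critical_stage(series)
      if (!is.na(det$critical_stage) &&
          isTRUE(sw$p_values[det$critical_stage] == 0)) {
        succ <- succ + 1L
      }
    }
    data.frame(noise_sd = noise_levels[l], successes = succ,
               replicates = replicates,
               success_fraction = succ / replicates)
  })
  do.call(rbind, rows)
}
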