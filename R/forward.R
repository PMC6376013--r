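#' Three-shell spherical head model
#'
#' Concentric-sphere volume-conductor model (brain, skull, scalp) used as the
#' analytic stand-in for realistic-geometry forward models. Potentials are
#' exact Legendre-series solutions of the piecewise-homogeneous Poisson
#' problem with an insulating outer boundary; the per-degree shell
#' coefficients are computed once at construction.
#'
#' @param shell_radii radii in mm of brain, outer skull and outer scalp
#'   surfaces, strictly increasing (default 80/85/92).
#' @param conductivities conductivities in S/m of brain, skull and scalp.
#'   The default uses 0.33 S/m soft tissue with a skull ratio of 1:25.
#' @param sensor_positions optional n x 3 matrix of electrode positions (mm)
#'   lying on the outer shell to within 1e-6 relative; when omitted, a
#'   deterministic quasi-uniform cap montage of `n_sensors` electrodes is
#'   generated with [cap_montage()].
#' @param n_sensors electrode count for the generated montage (default 256).
#' @param max_terms cap on the Legendre series order (default 200).
#' @return A `head_model` object.
#' @export
head_model <- function(shell_radii = c(80, 85, 92),
                       conductivities = c(0.33, 0.33 / 25, 0.33),
                       sensor_positions = NULL, n_sensors = 256,
                       max_terms = 200L) {
  if (length(shell_radii) != 3L || any(diff(shell_radii) <= 0)) {
    stop("`shell_radii` must be 3 strictly increasing radii", call. = FALSE)
  }
  if (length(conductivities) != 3L || any(conductivities <= 0)) {
    stop("`conductivities` must be 3 positive values", call. = FALSE)
  }
  if (is.null(sensor_positions)) {
    sensor_positions <- cap_montage(n_sensors, shell_radii[3])
  }
  sensor_positions <- as.matrix(sensor_positions)
  if (ncol(sensor_positions) != 3L) {
    stop("`sensor_positions` must be n x 3", call. = FALSE)
  }
  rad <- sqrt(rowSums(sensor_positions^2))
  if (any(abs(rad - shell_radii[3]) > 1e-6 * shell_radii[3])) {
    stop("all sensors must lie on the outer shell", call. = FALSE)
  }
  hm <- structure(
    list(shell_radii = shell_radii, conductivities = conductivities,
         sensors = sensor_positions, max_terms = as.integer(max_terms)),
    class = "head_model"
  )
  hm$coefs <- shell_series_coefs(hm)
  hm
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> 3-shell sphere, radii %s mm, conductivities %s S/m, %d sensors\n",
              paste(x$shell_radii, collapse = "/"),
              paste(signif(x$conductivities, 3), collapse = "/"),
              nrow(x$sensors)))
  invisible(x)
}

#' Deterministic quasi-uniform electrode cap
#'
#' Fibonacci-lattice covering of the upper portion of the sphere (about
#' 2.6 pi steradians, a geodesic-net-like cap extending below the equator),
#' giving a reproducible high-density montage without relying on any
#' manufacturer's coordinate files.
#'
#' @param n number of electrodes.
#' @param radius sphere radius in mm.
#' @param cap_cos cosine of the polar angle where the cap ends
#'   (default -0.3, i.e. a solid angle of 2.6 pi sr).
#' @return n x 3 matrix of positions in mm, head-centred RAS.
#' @export
cap_montage <- function(n, radius, cap_cos = -0.3) {
  stopifnot(n >= 4, radius > 0, cap_cos > -1, cap_cos < 1)
  i <- seq_len(n)
  z <- 1 - (i - 0.5) / n * (1 - cap_cos)
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(x = s * cos(phi), y = s * sin(phi), z = z)
}

# Per-degree surface coefficients C(n) of the 3-shell sphere: the surface
# potential for a unit source coefficient s (the r^-(n+1) multipole amplitude
# of the primary potential, lengths normalized to the outer radius). The
# boundary-value problem (continuity of V and sigma dV/dr at both interfaces,
# insulating outer boundary) is propagated outside-in, which keeps all
# intermediates on the scale of the interface radius ratios. In the
# equal-conductivity limit C(n) reduces to (2n+1)/n.
shell_series_coefs <- function(hm) {
  n <- seq_len(hm$max_terms)
  R <- hm$shell_radii[3]
  u1 <- hm$shell_radii[1] / R
  u2 <- hm$shell_radii[2] / R
  s1 <- hm$conductivities[1]
  s2 <- hm$conductivities[2]
  s3 <- hm$conductivities[3]
  # region 3 (scalp) with outer Neumann condition, amplitude fixed to 1
  v2 <- u2^n + n / (n + 1) * u2^(-(n + 1))
  d2 <- (s3 / s2) * (n * u2^(n - 1) - n * u2^(-(n + 2)))
  a <- ((n + 1) * v2 + d2 * u2) / (2 * n + 1)   # A2 u2^n
  b <- (n * v2 - d2 * u2) / (2 * n + 1)          # B2 u2^-(n+1)
  q <- u1 / u2
  v1 <- a * q^n + b * q^(-(n + 1))
  e1 <- (s2 / s1) * (n * a * q^n - (n + 1) * b * q^(-(n + 1)))
  (2 * n + 1)^2 * u1^(-(n + 1)) / ((n + 1) * (n * v1 - e1))
}

# Legendre-series sums for one dipole location: S1 (radial sum), Tn
# (tangential sum) per sensor, plus the geometry needed to assemble potentials
# for arbitrary moments. Truncated adaptively at relative term bound `tol`.
dipole_series <- function(hm, pos, tol = 1e-10, max_terms = hm$max_terms) {
  pos <- as.numeric(pos)
  b <- sqrt(sum(pos^2))
  if (b >= hm$shell_radii[1]) {
    stop("geometry error: source on or outside the brain shell", call. = FALSE)
  }
  R <- hm$shell_radii[3]
  x <- b / R
  r0hat <- if (b < 1e-9) c(0, 0, 1) else pos / b
  S <- hm$sensors / R
  cgam <- as.numeric(S %*% r0hat)
  cgam <- pmin(1, pmax(-1, cgam))
  ns <- nrow(S)
  S1 <- numeric(ns)
  Tn <- numeric(ns)
  Pm1 <- rep(1, ns)      # P_0
  P <- cgam              # P_1
  dPm1 <- rep(0, ns)     # P'_0
  dP <- rep(1, ns)       # P'_1
  sigma1 <- hm$conductivities[1]
  K <- 1000 / (4 * pi * sigma1 * R^2) # uV per nAm, lengths in mm
  total <- 0
  for (n in seq_len(max_terms)) {
    w <- hm$coefs[n] * x^(n - 1)
    S1 <- S1 + w * n * P
    Tn <- Tn + w * dP
    bound <- abs(w) * n * (n + 1) / 2
    total <- total + bound
    if (n >= 10 && bound < tol * total) break
    # ascend recurrences
    Pp <- ((2 * n + 1) * cgam * P - n * Pm1) / (n + 1)
    dPp <- dPm1 + (2 * n + 1) * P
    Pm1 <- P; P <- Pp
    dPm1 <- dP; dP <- dPp
  }
  D <- S - outer(cgam, r0hat) # sensor unit vectors minus radial projection
  list(S1 = S1, Tn = Tn, D = D, K = K, r0hat = r0hat)
}

#' Scalp potentials of a current dipole in the 3-shell sphere
#'
#' Exact series solution for the electric potential at the model's sensors
#' generated by a dipole at `pos` with moment `moment`. Linear in the moment.
#'
#' @param head a [head_model()].
#' @param pos dipole location, length-3 numeric in mm, strictly inside the
#'   brain shell.
#' @param moment dipole moment, length-3 numeric in nAm.
#' @param tol relative truncation tolerance of the Legendre series.
#' @param max_terms series order cap (defaults to the model's).
#' @return Numeric vector of sensor potentials in uV (unreferenced).
#' @export
dipole_potential <- function(head, pos, moment, tol = 1e-10,
                             max_terms = head$max_terms) {
  stopifnot(inherits(head, "head_model"))
  moment <- as.numeric(moment)
  if (length(moment) != 3L || any(!is.finite(moment))) {
    stop("`moment` must be a finite length-3 vector", call. = FALSE)
  }
  ds <- dipole_series(head, pos, tol = tol, max_terms = max_terms)
  m_r <- sum(moment * ds$r0hat)
  m_t <- moment - m_r * ds$r0hat
  ds$K * (m_r * ds$S1 + ds$Tn * as.numeric(ds$D %*% m_t))
}

#' Regular source-space grid inside the brain shell
#'
#' Equally spaced 3-D grid of solution points clipped to the brain
#' compartment, emulating a grey-matter solution space of roughly
#' `target_count` points (about 5000 in typical full-scale use). The spacing
#' is derived from the target count and refined so the realized count is
#' within 20 percent of the target.
#'
#' @param head a [head_model()].
#' @param target_count requested number of solution points (>= 10).
#' @return A `source_space`: `points` (p x 3 mm), `spacing` (mm) and integer
#'   `grid_index` (p x 3) used for neighbourhood/cluster connectivity.
#' @export
build_source_space <- function(head, target_count = 5000) {
  stopifnot(inherits(head, "head_model"))
  if (target_count < 10) stop("`target_count` must be >= 10", call. = FALSE)
  r1 <- head$shell_radii[1]
  build <- function(h) {
    m <- floor(r1 / h)
    g <- h * (-m:m)
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    pts[sqrt(rowSums(pts^2)) <= r1 - h / 2, , drop = FALSE]
  }
  h <- (4 * pi * r1^3 / (3 * target_count))^(1 / 3)
  best <- NULL
  best_score <- Inf
  for (iter in 1:40) {
    if (h < r1 / 60) break # resolution cap
    pts <- build(h)
    count <- nrow(pts)
    if (count >= 10) {
      score <- abs(log((count + 1) / target_count))
      if (score < best_score) {
        best <- list(pts = pts, h = h)
        best_score <- score
      }
    }
    if (count >= 0.8 * target_count && count <= 1.2 * target_count) break
    # damped multiplicative update; counts are lumpy at coarse resolution
    fac <- ((count + 1) / target_count)^(1 / 4)
    h <- h * min(max(fac, 0.75), 1.35)
  }
  if (is.null(best)) {
    stop("cannot reach the target count at feasible resolution",
         call. = FALSE)
  }
  structure(list(points = best$pts, spacing = best$h,
                 grid_index = round(best$pts / best$h)),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d points, %.1f mm spacing\n",
              nrow(x$points), x$spacing))
  invisible(x)
}

#' Assemble the lead field over a source space
#'
#' Stacks the average-referenced potentials of unit x/y/z dipoles at every
#' solution point into the sensors x (3 points) gain matrix used by the
#' inverse operator. Columns are ordered point-major: columns
#' `3(i-1)+1..3(i-1)+3` hold the x/y/z unit-moment potentials of point `i`.
#'
#' @param head a [head_model()].
#' @param src a [build_source_space()] result.
#' @param tol series truncation tolerance passed to the potential evaluator.
#' @return A `leadfield` object with the gain matrix (uV per nAm) and an
#'   average-reference flag.
#' @export
build_leadfield <- function(head, src, tol = 1e-10) {
  stopifnot(inherits(head, "head_model"), inherits(src, "source_space"))
  p <- nrow(src$points)
  ns <- nrow(head$sensors)
  gain <- matrix(0, ns, 3L * p)
  for (i in seq_len(p)) {
    ds <- tryCatch(dipole_series(head, src$points[i, ], tol = tol),
                   error = function(e) {
                     stop(sprintf("point %d: %s", i, conditionMessage(e)),
                          call. = FALSE)
                   })
    # unit moments assembled from the shared series
    mr <- ds$r0hat
    for (k in 1:3) {
      e_k <- numeric(3); e_k[k] <- 1
      m_r <- mr[k]
      m_t <- e_k - m_r * ds$r0hat
      gain[, 3L * (i - 1L) + k] <-
        ds$K * (m_r * ds$S1 + ds$Tn * as.numeric(ds$D %*% m_t))
    }
  }
  gain <- sweep(gain, 2L, colMeans(gain))
  structure(list(gain = gain, avg_ref = TRUE, n_sensors = ns,
                 n_points = p, units = "uV/nAm"),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d points x 3 (%s, average-referenced)\n",
              x$n_sensors, x$n_points, x$units))
  invisible(x)
}
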