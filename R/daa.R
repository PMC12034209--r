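#' Gaussian deformation kernel
#'
#' `K_sigma(x, y) = exp(-|x - y|^2 / sigma^2)`, exactly as printed (no
#' factor of two in the denominator).  Both the deformation kernel (width
#' `sigma`) and the data-attachment kernel (width `sigma_w`) use this form.
#'
#' @param x,y 3D points (length-3 vectors or n x 3 matrices, paired rows).
#' @param sigma Kernel width, mm (> 0).
#' @return Scalar or vector in (0, 1].
#' @export
gaussian_kernel <- function(x, y, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  x <- rbind(x); y <- rbind(y)
  unname(exp(-rowSums((x - y)^2) / sigma^2))
}

# full kernel matrix K(a_i, b_j)
gauss_km <- function(a, b, sigma) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  exp(-pmax(d2, 0) / sigma^2)
}

#' Initialise control points on a regular grid
#'
#' Axis-aligned grid with spacing `sigma` covering the template bounding box
#' padded by `pad` per side (default `sigma / 2`); per-axis node count is
#' `ceiling(padded extent / sigma) + 1`.  Smaller kernel widths therefore
#' yield more control points.  Deterministic.
#'
#' @param template A [mesh3t()].
#' @param sigma Deformation kernel width, mm.
#' @param pad Padding per side, mm (default `sigma / 2`).
#' @return `p x 3` matrix of control-point positions.
#' @export
init_control_points <- function(template, sigma, pad = sigma / 2) {
  if (sigma <= 0) stop("sigma must be positive")
  bb <- mesh_bbox(template)
  lo <- bb["lo", ] - pad
  hi <- bb["hi", ] + pad
  counts <- pmax(ceiling((hi - lo) / sigma) + 1, 2)
  axes <- lapply(1:3, function(d) lo[d] + (seq_len(counts[d]) - 1) * sigma)
  g <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  dimnames(g) <- list(NULL, c("x", "y", "z"))
  g
}

#' Velocity field generated by control points and momenta
#'
#' `X(x) = sum_i K(x, q_i) mu_i`: the Gaussian-smoothed superposition of the
#' momentum vectors, linear in the momenta.
#'
#' @param x Points at which to evaluate (`n x 3`).
#' @param q Control-point positions (`p x 3`).
#' @param mu Momenta (`p x 3`).
#' @param sigma Kernel width, mm.
#' @return `n x 3` matrix of velocities.
#' @export
velocity_field <- function(x, q, mu, sigma) {
  gauss_km(rbind(x), q, sigma) %*% mu
}

#' Hamiltonian of a control-point/momenta state
#'
#' `H = 1/2 sum_ij K(q_i, q_j) mu_i . mu_j`, the kinetic energy conserved
#' along geodesics.
#'
#' @inheritParams velocity_field
#' @return Scalar.
#' @export
hamiltonian <- function(q, mu, sigma) {
  sum(gauss_km(q, q, sigma) * tcrossprod(mu)) / 2
}

# right-hand side of the joint (q, mu, x) Hamiltonian system; the kernel
# matrices are returned so the adjoint pass can reuse them
shoot_rhs <- function(st, sigma) {
  q <- st$q; mu <- st$mu
  Kq <- gauss_km(q, q, sigma)
  M <- tcrossprod(mu)
  W <- Kq * M
  Fq <- Kq %*% mu
  Fmu <- (2 / sigma^2) * (rowSums(W) * q - W %*% q)
  Kx <- if (is.null(st$x)) NULL else gauss_km(st$x, q, sigma)
  Fx <- if (is.null(st$x)) NULL else Kx %*% mu
  list(f = list(q = Fq, mu = Fmu, x = Fx), Kq = Kq, Kx = Kx)
}

# vector-Jacobian product of shoot_rhs: given cotangents of the outputs,
# accumulate cotangents of (q, mu, x); kernels may be passed in from the
# forward pass
shoot_vjp <- function(st, cot, sigma, Kq = NULL, Kx = NULL) {
  q <- st$q; mu <- st$mu; x <- st$x
  p <- nrow(q)
  s2 <- sigma^2
  if (is.null(Kq)) Kq <- gauss_km(q, q, sigma)
  bq <- matrix(0, p, 3); bmu <- matrix(0, p, 3)
  bx <- NULL
  aq <- cot$q; amu <- cot$mu; ax <- cot$x
  # d<ax, K(x,q) mu>
  if (!is.null(x) && !is.null(ax)) {
    if (is.null(Kx)) Kx <- gauss_km(x, q, sigma)
    G <- Kx * (ax %*% t(mu))
    bx <- (-2 / s2) * (rowSums(G) * x - G %*% q)
    bq <- bq + (2 / s2) * (crossprod(G, x) - colSums(G) * q)
    bmu <- bmu + crossprod(Kx, ax)
  }
  # d<aq, K(q,q) mu>
  if (!is.null(aq)) {
    Gq <- Kq * (aq %*% t(mu))
    H2 <- Gq + t(Gq)
    bmu <- bmu + crossprod(Kq, aq)
    bq <- bq + (-2 / s2) * (rowSums(H2) * q - H2 %*% q)
  }
  # d<amu, mu-dot>
  if (!is.null(amu)) {
    M <- tcrossprod(mu)
    B <- rowSums(amu * q) - amu %*% t(q)
    C <- Kq * B
    bmu <- bmu + (2 / s2) * ((C + t(C)) %*% mu)
    P <- (2 / s2) * Kq * M
    E <- (-4 / s2^2) * Kq * M * B
    HE <- E + t(E)
    bq <- bq + rowSums(P) * amu - crossprod(P, amu) +
      rowSums(HE) * q - HE %*% q
  }
  list(q = bq, mu = bmu, x = bx)
}

st_add <- function(a, b, s) {
  out <- list(q = a$q + s * b$q, mu = a$mu + s * b$mu)
  out$x <- if (is.null(a$x)) NULL else a$x + s * b$x
  out
}

# forward integration storing the stage states (and, when `keep_kernels`,
# their kernel matrices) needed by the adjoint pass
shoot_forward <- function(q0, mu0, x0, sigma, n_steps, integrator,
                          keep_kernels = FALSE) {
  h <- 1 / n_steps
  st <- list(q = q0, mu = mu0, x = x0)
  states <- vector("list", n_steps + 1L)
  mids <- vector("list", n_steps)
  K_at_state <- vector("list", n_steps)
  K_at_mid <- vector("list", n_steps)
  states[[1]] <- st
  for (s in seq_len(n_steps)) {
    if (integrator == "euler") {
      r <- shoot_rhs(st, sigma)
      if (keep_kernels) K_at_state[[s]] <- r[c("Kq", "Kx")]
      st <- st_add(st, r$f, h)
    } else {
      r1 <- shoot_rhs(st, sigma)
      if (keep_kernels) K_at_state[[s]] <- r1[c("Kq", "Kx")]
      mid <- st_add(st, r1$f, h / 2)
      mids[[s]] <- mid
      r2 <- shoot_rhs(mid, sigma)
      if (keep_kernels) K_at_mid[[s]] <- r2[c("Kq", "Kx")]
      st <- st_add(st, r2$f, h)
    }
    if (any(!is.finite(st$q)) || any(!is.finite(st$mu)))
      stop_morpho(sprintf("non-finite state at integration step %d", s),
                  "integration_diverged")
    states[[s + 1L]] <- st
  }
  list(states = states, mids = mids, K_at_state = K_at_state,
       K_at_mid = K_at_mid, h = h, integrator = integrator, sigma = sigma)
}

# adjoint (reverse) pass: cotangent of the final state back to t = 0
shoot_backward <- function(fwd, cot_final) {
  h <- fwd$h
  sigma <- fwd$sigma
  a <- cot_final
  n_steps <- length(fwd$states) - 1L
  for (s in rev(seq_len(n_steps))) {
    y <- fwd$states[[s]]
    Ky <- fwd$K_at_state[[s]]
    Km <- fwd$K_at_mid[[s]]
    if (fwd$integrator == "euler") {
      w <- shoot_vjp(y, a, sigma, Ky$Kq, Ky$Kx)
      a <- list(q = a$q + h * w$q, mu = a$mu + h * w$mu,
                x = if (is.null(a$x)) NULL else a$x + h * w$x)
    } else {
      w <- shoot_vjp(fwd$mids[[s]], a, sigma, Km$Kq, Km$Kx)
      w2 <- shoot_vjp(y, w, sigma, Ky$Kq, Ky$Kx)
      a <- list(q = a$q + h * w$q + h^2 / 2 * w2$q,
                mu = a$mu + h * w$mu + h^2 / 2 * w2$mu,
                x = if (is.null(a$x)) NULL else
                  a$x + h * w$x + h^2 / 2 * w2$x)
    }
  }
  a
}

#' Geodesic shooting of control points and momenta
#'
#' Integrates the Hamiltonian system
#' `q-dot = K(q, q) mu`,
#' `mu-dot = -1/2 grad_q (K(q, q) mu' mu)`
#' over t in 0..1 with Euler or midpoint Runge-Kutta (rk2) steps.  With a
#' single control point the gradient term vanishes and the flow is the exact
#' translation `q0 + mu0`; in general the Hamiltonian and the total momentum
#' are conserved up to integration error.
#'
#' @param q0 Initial control points (`p x 3`).
#' @param mu0 Initial momenta (`p x 3`).
#' @param sigma Kernel width, mm.
#' @param n_steps Number of time steps (default 10).
#' @param integrator `"rk2"` (default) or `"euler"`.
#' @return Object of class `daa_trajectory`: `t` (times), `q` and `mu`
#'   (lists of states per time), plus the shooting settings.
#' @export
geodesic_shoot <- function(q0, mu0, sigma, n_steps = 10L,
                           integrator = c("rk2", "euler")) {
  integrator <- match.arg(integrator)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  q0 <- rbind(q0); mu0 <- rbind(mu0)
  stopifnot(nrow(q0) == nrow(mu0))
  if (any(!is.finite(mu0))) stop("non-finite momenta")
  fwd <- shoot_forward(q0, mu0, NULL, sigma, n_steps, integrator)
  structure(list(t = seq(0, 1, length.out = n_steps + 1L),
                 q = lapply(fwd$states, `[[`, "q"),
                 mu = lapply(fwd$states, `[[`, "mu"),
                 q0 = q0, mu0 = mu0, sigma = sigma, n_steps = n_steps,
                 integrator = integrator),
            class = "daa_trajectory")
}

#' Advect a mesh along a geodesic flow
#'
#' Each vertex is carried by the ambient velocity field
#' `x-dot = sum_i K(x, q_i(t)) mu_i(t)` with the same integrator and step
#' count as the trajectory; connectivity is unchanged.
#'
#' @param mesh A [mesh3t()].
#' @param trajectory A `daa_trajectory` from [geodesic_shoot()].
#' @return The deformed [mesh3t()].
#' @export
flow_mesh <- function(mesh, trajectory) {
  fwd <- shoot_forward(trajectory$q0, trajectory$mu0, mesh$vertices,
                       trajectory$sigma, trajectory$n_steps,
                       trajectory$integrator)
  v1 <- fwd$states[[length(fwd$states)]]$x
  mesh3t(v1, mesh$faces, specimen_id = mesh$specimen_id)
}

as_face_set <- function(x) {
  if (inherits(x, "mesh3t")) suppressWarnings(oriented_face_set(x)) else x
}

#' Current and varifold distances between oriented surfaces
#'
#' Kernel discrepancies between the oriented face measures of two meshes:
#' with `K_W` the Gaussian kernel of width `sigma_w`, the current pairing is
#' `K_W(c_p, c_q) (n_p . n_q)` and the varifold pairing
#' `K_W(c_p, c_q) (n_p . n_q)^2 / (|n_p| |n_q|)`; the printed double sums
#' are the RKHS inner products `<A, B>`, and the squared distance is the
#' bilinear expansion `<A,A> - 2<A,B> + <B,B>`.  Symmetric, non-negative,
#' zero on identical face sets; requires no point correspondence.  Zero-area
#' faces are skipped in varifold mode.
#'
#' @param a,b [mesh3t()] objects or oriented face sets (see
#'   [oriented_face_set()]).
#' @param sigma_w Attachment kernel width, mm.
#' @param mode `"varifold"` (orientation-robust default) or `"current"`.
#' @return Non-negative scalar (squared-distance scale).
#' @export
mesh_attachment_distance <- function(a, b, sigma_w,
                                     mode = c("varifold", "current")) {
  mode <- match.arg(mode)
  if (sigma_w <= 0) stop("sigma_w must be positive")
  A <- as_face_set(a); B <- as_face_set(b)
  if (nrow(A$centres) == 0L || nrow(B$centres) == 0L)
    stop("empty face set")
  max(cpp_attachment(A$centres, A$normals, B$centres, B$normals, sigma_w,
                     mode == "varifold"), 0)
}

#' Precompute the specimen-side attachment terms
#'
#' The `<B,B>` self inner products and oriented face sets of the specimens
#' are constant during atlas fitting; computing them once saves a third of
#' every attachment evaluation.
#'
#' @param specimens List of [mesh3t()].
#' @param sigma_w Attachment kernel width, mm.
#' @param attachment `"varifold"` or `"current"`.
#' @return List with `fsets` and `bb`.
#' @export
attachment_cache <- function(specimens, sigma_w, attachment = "varifold") {
  fsets <- lapply(specimens, as_face_set)
  bb <- vapply(fsets, function(fs)
    cpp_self_inner(fs$centres, fs$normals, sigma_w,
                   attachment == "varifold"), 0)
  list(fsets = fsets, bb = bb)
}

# attachment value + gradient with respect to mesh A's VERTICES
attachment_grad_vertices <- function(meshA, faceB, sigma_w, varifold,
                                     bb = NA_real_) {
  ofs <- suppressWarnings(oriented_face_set(meshA))
  res <- cpp_attachment_grad(ofs$centres, ofs$normals, faceB$centres,
                             faceB$normals, sigma_w, varifold, bb = bb)
  f <- meshA$faces
  v <- meshA$vertices
  gc <- res$grad_centres
  gn <- res$grad_normals
  gv <- matrix(0, nrow(v), 3)
  v1 <- v[f[, 1], , drop = FALSE]; v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  contrib <- list(gc / 3 + cr(v2 - v3, gn) / 2,
                  gc / 3 + cr(v3 - v1, gn) / 2,
                  gc / 3 + cr(v1 - v2, gn) / 2)
  for (k in 1:3)
    for (d in 1:3)
      gv[, d] <- gv[, d] + tapply_add(contrib[[k]][, d], f[, k], nrow(v))
  list(value = max(res$value, 0), grad = gv)
}

#' Deterministic atlas model
#'
#' Container for the output of [estimate_atlas()]: the estimated template
#' mesh, the control points, one momenta set per specimen, the kernel
#' specification, the noise parameter, the attachment mode and the per-
#' iteration loss trace.
#'
#' @param template A [mesh3t()].
#' @param control_points `p x 3` matrix.
#' @param momenta List (length n) of `p x 3` matrices.
#' @param kernel List with `sigma` and `sigma_w` (both mm, > 0).
#' @param noise_sigma Data-term noise scale (dimensionless; printed run
#'   setting 10.0).
#' @param attachment `"varifold"` or `"current"`.
#' @param n_steps,integrator Shooting discretisation.
#' @param loss_trace Numeric vector of accepted total losses.
#' @return Object of class `daa_atlas`.
#' @export
daa_atlas <- function(template, control_points, momenta, kernel,
                      noise_sigma = 10, attachment = "varifold",
                      n_steps = 10L, integrator = "rk2",
                      loss_trace = numeric(0)) {
  stopifnot(kernel$sigma > 0, kernel$sigma_w > 0)
  momenta <- lapply(momenta, rbind)
  stopifnot(all(vapply(momenta, nrow, 1L) == nrow(control_points)))
  structure(list(template = template,
                 control_points = rbind(control_points), momenta = momenta,
                 kernel = kernel, noise_sigma = noise_sigma,
                 attachment = attachment, n_steps = n_steps,
                 integrator = integrator, loss_trace = loss_trace),
            class = "daa_atlas")
}

#' @export
print.daa_atlas <- function(x, ...) {
  cat(sprintf(paste0("<daa_atlas> %d specimens, %d control points, sigma = ",
                     "%g mm, sigma_w = %g mm, %s attachment\n"),
              length(x$momenta), nrow(x$control_points), x$kernel$sigma,
              x$kernel$sigma_w, x$attachment))
  if (length(x$loss_trace))
    cat(sprintf("  loss: %.6g -> %.6g in %d accepted iterations\n",
                x$loss_trace[1], x$loss_trace[length(x$loss_trace)],
                length(x$loss_trace) - 1L))
  invisible(x)
}

#' Atlas loss: data attachment plus deformation regularity
#'
#' `f(T, q, mu) = sum_i [ d^2(Phi_{q,mu_i}(T), C_i) / (2 noise^2) +
#' 1/2 mu_i' K(q, q) mu_i ]`: the attachment distance between the flowed
#' template and each specimen, weighted by the noise parameter, plus the
#' kinetic energy of each specimen's initial momenta as the regulariser.
#'
#' @param model A [daa_atlas()].
#' @param specimens List of [mesh3t()] meshes, same order as the momenta.
#' @param .cache Optional precomputed attachment cache from
#'   [attachment_cache()] (used internally during fitting).
#' @return List with `total`, `data_terms`, `regularity_terms`.
#' @export
atlas_loss <- function(model, specimens, .cache = NULL) {
  stopifnot(length(specimens) == length(model$momenta))
  q <- model$control_points
  Kq <- gauss_km(q, q, model$kernel$sigma)
  varifold <- model$attachment == "varifold"
  cache <- .cache %||% attachment_cache(specimens, model$kernel$sigma_w,
                                        model$attachment)
  fsets <- cache$fsets
  data_terms <- regularity_terms <- numeric(length(specimens))
  for (i in seq_along(specimens)) {
    mu <- model$momenta[[i]]
    fwd <- shoot_forward(q, mu, model$template$vertices,
                         model$kernel$sigma, model$n_steps, model$integrator)
    v1 <- fwd$states[[length(fwd$states)]]$x
    flowed <- suppressWarnings(
      oriented_face_set(mesh3t(v1, model$template$faces)))
    d2 <- max(cpp_attachment(flowed$centres, flowed$normals,
                             fsets[[i]]$centres, fsets[[i]]$normals,
                             model$kernel$sigma_w, varifold,
                             bb = cache$bb[i]), 0)
    data_terms[i] <- d2 / (2 * model$noise_sigma^2)
    regularity_terms[i] <- sum(Kq * tcrossprod(mu)) / 2
  }
  list(total = sum(data_terms) + sum(regularity_terms),
       data_terms = data_terms, regularity_terms = regularity_terms)
}

#' Gradient of the atlas loss
#'
#' Hand-derived adjoint of the discretised forward computation: the
#' attachment gradient with respect to the flowed template vertices is
#' pulled back through the Runge-Kutta shooting steps to the template
#' vertices, control points and per-specimen momenta, and the regulariser's
#' closed-form gradients are added.  Agrees with central finite differences
#' (a tested contract).
#'
#' @inheritParams atlas_loss
#' @return List with `loss` (as [atlas_loss()]), `grad_template` (`V x 3`),
#'   `grad_control_points` (`p x 3`), `grad_momenta` (list of `p x 3`).
#' @export
atlas_gradient <- function(model, specimens, .cache = NULL) {
  q <- model$control_points
  sigma <- model$kernel$sigma
  Kq <- gauss_km(q, q, sigma)
  varifold <- model$attachment == "varifold"
  cache <- .cache %||% attachment_cache(specimens, model$kernel$sigma_w,
                                        model$attachment)
  fsets <- cache$fsets
  n <- length(specimens)
  gT <- matrix(0, nrow(model$template$vertices), 3)
  gq <- matrix(0, nrow(q), 3)
  gmu <- vector("list", n)
  data_terms <- regularity_terms <- numeric(n)
  for (i in seq_len(n)) {
    mu <- model$momenta[[i]]
    fwd <- shoot_forward(q, mu, model$template$vertices, sigma,
                         model$n_steps, model$integrator,
                         keep_kernels = TRUE)
    v1 <- fwd$states[[length(fwd$states)]]$x
    flowed <- mesh3t(v1, model$template$faces)
    ag <- attachment_grad_vertices(flowed, fsets[[i]],
                                   model$kernel$sigma_w, varifold,
                                   bb = cache$bb[i])
    w <- 1 / (2 * model$noise_sigma^2)
    data_terms[i] <- ag$value * w
    cot <- shoot_backward(fwd, list(q = matrix(0, nrow(q), 3),
                                    mu = matrix(0, nrow(q), 3),
                                    x = ag$grad * w))
    M <- tcrossprod(mu)
    KM <- Kq * M
    regularity_terms[i] <- sum(KM) / 2
    gmu[[i]] <- cot$mu + Kq %*% mu
    gq <- gq + cot$q + (-2 / sigma^2) * (rowSums(KM) * q - KM %*% q)
    gT <- gT + cot$x
  }
  list(loss = list(total = sum(data_terms) + sum(regularity_terms),
                   data_terms = data_terms,
                   regularity_terms = regularity_terms),
       grad_template = gT, grad_control_points = gq, grad_momenta = gmu)
}

#' Estimate a deterministic atlas from a mesh population
#'
#' Joint gradient descent on the template vertices, the control-point
#' positions and all per-specimen momenta, minimising [atlas_loss()].
#' Momenta start at zero and the template at the supplied mesh (typically a
#' specimen; template choice is a configuration option).  Each iteration
#' runs an adaptive line search along the negative gradient: the step is
#' halved until the loss decreases, then doubled greedily while that keeps
#' improving, so the step size self-tunes across iterations from the
#' initial `step`; each parameter block moves on its own scale, fixed by
#' the first non-zero gradient of that block.  Deterministic: no randomness
#' anywhere.
#'
#' @param specimens List of [mesh3t()] meshes (>= 2).
#' @param initial_template [mesh3t()] to initialise the template
#'   (watertight recommended).
#' @param kernel List with `sigma` and `sigma_w` (mm); `sigma_w` defaults to
#'   `sigma / 2` if missing.
#' @param max_iter Outer iterations (printed run setting: 150).
#' @param step Initial step size (printed run setting: 0.01).
#' @param noise_sigma Noise parameter (printed run setting: 10.0).
#' @param attachment `"varifold"` (default) or `"current"`.
#' @param n_steps,integrator Shooting discretisation (default 10 rk2 steps).
#' @param optimize_control_points Also move control points (default TRUE)?
#' @param optimize_template Also move template vertices (default TRUE)?
#' @param control_points Optional `p x 3` start positions; default
#'   [init_control_points()] on the template.
#' @param tol Relative loss-change stopping threshold (default 1e-6).
#' @return A fitted [daa_atlas()] with `loss_trace`.
#' @export
estimate_atlas <- function(specimens, initial_template, kernel,
                           max_iter = 150L, step = 0.01, noise_sigma = 10,
                           attachment = c("varifold", "current"),
                           n_steps = 10L, integrator = "rk2",
                           optimize_control_points = TRUE,
                           optimize_template = TRUE,
                           control_points = NULL, tol = 1e-6) {
  attachment <- match.arg(attachment)
  if (length(specimens) < 2L) stop("need at least 2 specimens")
  if (is.null(kernel$sigma_w)) kernel$sigma_w <- kernel$sigma / 2
  q <- control_points %||% init_control_points(initial_template, kernel$sigma)
  p <- nrow(q)
  n <- length(specimens)
  mu <- replicate(n, matrix(0, p, 3), simplify = FALSE)
  model <- daa_atlas(initial_template, q, mu, kernel, noise_sigma,
                     attachment, n_steps, integrator)
  cache <- attachment_cache(specimens, kernel$sigma_w, attachment)
  gr <- atlas_gradient(model, specimens, .cache = cache)
  if (!is.finite(gr$loss$total))
    stop_morpho("non-finite loss at iteration 0", "divergence")
  current <- gr$loss$total
  trace <- current
  make_cand <- function(s) {
    cand <- model
    cand$momenta <- purrr::map2(model$momenta, gr$grad_momenta,
                                ~ .x - s * sc_mu * .y)
    if (optimize_control_points)
      cand$control_points <- model$control_points -
        s * sc_q * gr$grad_control_points
    if (optimize_template)
      cand$template$vertices <- model$template$vertices -
        s * sc_T * gr$grad_template
    cand
  }
  eval_cand <- function(cand, it) {
    l <- tryCatch(atlas_loss(cand, specimens, .cache = cache)$total,
                  morphoatlas_error_integration_diverged = function(e) Inf)
    if (is.nan(l))
      stop_morpho(sprintf("loss became NaN at iteration %d", it),
                  "divergence")
    l
  }
  for (it in seq_len(max_iter)) {
    # per-block scales from the current gradient, so each block moves on
    # its own (inf-norm) scale throughout the fit
    sc_T <- block_scale(gr$grad_template)
    sc_q <- block_scale(gr$grad_control_points)
    sc_mu <- block_scale(do.call(rbind, gr$grad_momenta))
    # halve until the step decreases the loss ...
    accepted <- FALSE
    for (try in 1:30) {
      cand <- make_cand(step)
      cand_loss <- eval_cand(cand, it)
      if (cand_loss < current) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    # ... then expand greedily while that keeps improving
    for (try in 1:12) {
      cand2 <- make_cand(step * 2)
      l2 <- eval_cand(cand2, it)
      if (l2 < cand_loss) {
        step <- step * 2
        cand <- cand2
        cand_loss <- l2
      } else break
    }
    rel <- (current - cand_loss) / max(abs(current), .Machine$double.eps)
    model <- cand
    current <- cand_loss
    trace <- c(trace, current)
    if (rel < tol) break
    if (it < max_iter) gr <- atlas_gradient(model, specimens,
                                            .cache = cache)
  }
  model$loss_trace <- trace
  model
}

block_scale <- function(g) {
  m <- max(abs(g))
  if (m == 0) 0 else 1 / m
}
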