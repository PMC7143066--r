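# Desk-scale planar flow and species transport in the obstructed channel.
#
# Flow: steady creeping (Stokes) flow in streamfunction-vorticity form on the
# node grid, solved as one sparse linear system: Laplacian(psi) + omega = 0 and
# Laplacian(omega) = 0 in the fluid, psi Dirichlet on walls (0 on the bottom
# wall and bottom obstacles, the 2-D flow rate on the top side), a developed
# parabolic inlet profile and zero-gradient outflow. No-slip enters through
# the wall vorticity closure (Jensen's second-order formula, falling back to
# Thom's first-order one where the stencil is cut short). At the device's
# Reynolds numbers (order 10) inertia is neglected; with constant viscosity the
# streamfunction field is then independent of the fluid properties and set by
# the flow rate alone.
#
# Transport: steady advection-diffusion by finite volumes on the cell grid,
# with face fluxes taken as streamfunction differences (exactly divergence
# free, so the convection operator conserves mass to machine precision) and
# first-order upwinding (bounded, monotone; the numerical diffusion this adds
# is the price of boundedness at coarse desk resolution).

#' Solve the steady laminar flow field
#'
#' @param geom a [build_geometry()] channel.
#' @param tfr total flow rate (mL/h).
#' @param frr flow rate ratio (stored for downstream transport; the merged
#'   flow field itself depends only on TFR).
#' @param properties a [property_model()]; used to evaluate the Reynolds
#'   number at the reference composition.
#' @param ny transverse cells, passed to [discretize_geometry()] (ignored if
#'   `grid` is given).
#' @param grid optionally a prebuilt `channel_grid`, so one discretisation can
#'   be shared between solves.
#' @param c_ref reference ethanol mass fraction for property evaluation;
#'   default the fully mixed outlet composition `1 / (1 + frr)`.
#' @return An object of class `flow_field`: the streamfunction on nodes (solid
#'   nodes filled with their wall value), cell-centred velocities, flow
#'   diagnostics (Reynolds number, flux balance, divergence residual).
#' @export
solve_flow <- function(geom, tfr, frr, properties = property_model(),
                       ny = 30, grid = NULL, c_ref = 1 / (1 + frr)) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (!is.numeric(tfr) || tfr <= 0 || !is.numeric(frr) || frr <= 0) {
    stop_invalid("'tfr' and 'frr' must be positive")
  }
  g <- if (is.null(grid)) discretize_geometry(geom, ny = ny) else grid
  stopifnot(inherits(g, "channel_grid"))

  q3 <- tfr * 1e-6 / 3600          # mL/h -> m3/s
  q2 <- q3 / geom$depth            # planar flow rate, m2/s
  w <- geom$width
  props <- mixture_properties(properties, c_ref)
  u_mean <- q3 / (w * geom$depth)
  reynolds <- props$density * u_mean * w / props$viscosity
  if (reynolds > 200) {
    warning(sprintf(
      "Reynolds number %.0f: the creeping-flow approximation is questionable",
      reynolds
    ), call. = FALSE)
  }

  nxn <- g$nx + 1L
  nyn <- g$ny + 1L
  # the linear system is assembled in dimensionless form (lengths scaled by
  # the channel width, streamfunction by the planar flow rate) so that psi,
  # omega and the stencil coefficients are all of order one
  solid <- g$node_solid
  wall <- g$node_wall
  id <- matrix(NA_integer_, nxn, nyn)
  id[!solid] <- seq_len(sum(!solid))
  nf <- sum(!solid)
  P <- function(i, j) id[cbind(i, j)]          # psi unknown index
  W <- function(i, j) id[cbind(i, j)] + nf     # omega unknown index

  eta <- g$yn / w
  psi_in <- 3 * eta^2 - 2 * eta^3
  omega_in <- -(6 - 12 * eta)
  psi_wall_value <- ifelse(g$node_bottom, 0, 1)

  # triplet accumulators
  ti <- tj <- tv <- vector("list", 0L)
  rhs <- numeric(2 * nf)
  row_of <- c(psi = 0L, omega = nf)
  add <- function(rows, cols, vals) {
    ti[[length(ti) + 1L]] <<- rows
    tj[[length(tj) + 1L]] <<- cols
    tv[[length(tv) + 1L]] <<- vals
  }

  idx_mat <- function(mask) which(mask, arr.ind = TRUE)

  is_inlet <- matrix(FALSE, nxn, nyn); is_inlet[1, ] <- TRUE
  is_outlet <- matrix(FALSE, nxn, nyn); is_outlet[nxn, ] <- TRUE
  cat_wall <- wall & !solid
  cat_inlet <- is_inlet & !solid & !cat_wall
  cat_outlet <- is_outlet & !solid & !cat_wall
  cat_int <- !solid & !cat_wall & !cat_inlet & !cat_outlet

  dx2 <- (g$dx / w)^2; dy2 <- (g$dy / w)^2

  ## --- psi equations ---
  m <- idx_mat(cat_wall)
  add(P(m[, 1], m[, 2]), P(m[, 1], m[, 2]), rep(1, nrow(m)))
  rhs[P(m[, 1], m[, 2])] <- psi_wall_value[m]

  m <- idx_mat(cat_inlet)
  add(P(m[, 1], m[, 2]), P(m[, 1], m[, 2]), rep(1, nrow(m)))
  rhs[P(m[, 1], m[, 2])] <- psi_in[m[, 2]]

  m <- idx_mat(cat_outlet)
  add(P(m[, 1], m[, 2]), P(m[, 1], m[, 2]), rep(1, nrow(m)))
  add(P(m[, 1], m[, 2]), P(m[, 1] - 1L, m[, 2]), rep(-1, nrow(m)))

  m <- idx_mat(cat_int)
  i <- m[, 1]; j <- m[, 2]
  rowsP <- P(i, j)
  add(rowsP, rowsP, rep(-2 / dx2 - 2 / dy2, nrow(m)))
  add(rowsP, P(i + 1L, j), rep(1 / dx2, nrow(m)))
  add(rowsP, P(i - 1L, j), rep(1 / dx2, nrow(m)))
  add(rowsP, P(i, j + 1L), rep(1 / dy2, nrow(m)))
  add(rowsP, P(i, j - 1L), rep(1 / dy2, nrow(m)))
  add(rowsP, W(i, j), rep(1, nrow(m)))

  ## --- omega equations ---
  m <- idx_mat(cat_inlet)
  add(W(m[, 1], m[, 2]), W(m[, 1], m[, 2]), rep(1, nrow(m)))
  rhs[W(m[, 1], m[, 2])] <- omega_in[m[, 2]]

  m <- idx_mat(cat_outlet)
  add(W(m[, 1], m[, 2]), W(m[, 1], m[, 2]), rep(1, nrow(m)))
  add(W(m[, 1], m[, 2]), W(m[, 1] - 1L, m[, 2]), rep(-1, nrow(m)))

  m <- idx_mat(cat_int)
  i <- m[, 1]; j <- m[, 2]
  rowsW <- W(i, j)
  add(rowsW, rowsW, rep(-2 / dx2 - 2 / dy2, nrow(m)))
  add(rowsW, W(i + 1L, j), rep(1 / dx2, nrow(m)))
  add(rowsW, W(i - 1L, j), rep(1 / dx2, nrow(m)))
  add(rowsW, W(i, j + 1L), rep(1 / dy2, nrow(m)))
  add(rowsW, W(i, j - 1L), rep(1 / dy2, nrow(m)))

  # wall vorticity closure, node by node (wall nodes are a small minority)
  pad_solid_cell <- matrix(TRUE, g$nx + 2, g$ny + 2)
  pad_solid_cell[2:(g$nx + 1), 2:(g$ny + 1)] <- g$cell_solid
  pad_solid_cell[1, 2:(g$ny + 1)] <- g$cell_solid[1, ]
  pad_solid_cell[g$nx + 2, 2:(g$ny + 1)] <- g$cell_solid[g$nx, ]
  seg_fluid <- function(i, j, d) {
    # are both cells flanking the node segment (i,j) -> (i,j)+d fluid?
    fl <- switch(d,
      "+x" = rbind(c(i + 1, j), c(i + 1, j + 1)),
      "-x" = rbind(c(i, j), c(i, j + 1)),
      "+y" = rbind(c(i, j + 1), c(i + 1, j + 1)),
      "-y" = rbind(c(i, j), c(i + 1, j))
    )
    !any(pad_solid_cell[fl])
  }
  dirs <- list("+x" = c(1L, 0L), "-x" = c(-1L, 0L),
               "+y" = c(0L, 1L), "-y" = c(0L, -1L))
  opp <- c("+x" = "-x", "-x" = "+x", "+y" = "-y", "-y" = "+y")
  mw <- idx_mat(cat_wall)
  for (r in seq_len(nrow(mw))) {
    i <- mw[r, 1]; j <- mw[r, 2]
    row <- W(i, j)
    contribs <- list()
    for (d in names(dirs)) {
      dd <- dirs[[d]]
      h2 <- if (dd[1] != 0) dx2 else dy2
      i1 <- i + dd[1]; j1 <- j + dd[2]
      in_dom <- i1 >= 1 && i1 <= nxn && j1 >= 1 && j1 <= nyn
      if (!in_dom || !seg_fluid(i, j, d) || seg_fluid(i, j, opp[d])) next
      i2 <- i + 2L * dd[1]; j2 <- j + 2L * dd[2]
      have2 <- i2 >= 1 && i2 <= nxn && j2 >= 1 && j2 <= nyn &&
        !solid[i2, j2]
      if (have2) { # Jensen, second order
        contribs[[length(contribs) + 1]] <- list(
          cols = c(P(i, j), P(i1, j1), P(i2, j2)),
          vals = c(7, -8, 1) / (2 * h2)
        )
      } else {     # Thom, first order
        contribs[[length(contribs) + 1]] <- list(
          cols = c(P(i, j), P(i1, j1)),
          vals = c(2, -2) / h2
        )
      }
    }
    add(row, row, 1)
    if (length(contribs)) {
      for (ct in contribs) add(rep(row, length(ct$cols)), ct$cols,
                               -ct$vals / length(contribs))
    }
  }

  A <- Matrix::sparseMatrix(
    i = unlist(ti), j = unlist(tj), x = unlist(tv),
    dims = c(2 * nf, 2 * nf)
  )
  z <- as.numeric(Matrix::solve(A, rhs))
  lin_res <- max(abs(A %*% z - rhs))

  psi <- matrix(NA_real_, nxn, nyn)
  psi[!solid] <- q2 * z[seq_len(nf)]
  psi[solid] <- ifelse(g$node_bottom[solid], 0, q2)
  omega <- matrix(NA_real_, nxn, nyn)
  omega[!solid] <- q2 / w^2 * z[nf + seq_len(nf)]

  # cell-centred velocities from face fluxes (streamfunction differences)
  fe <- psi[-1, -1] - psi[-1, -nyn]          # east-face flux of each cell
  fw <- psi[-nxn, -1] - psi[-nxn, -nyn]      # west-face flux
  gn <- -(psi[-1, -1] - psi[-nxn, -1])       # north-face flux
  gs <- -(psi[-1, -nyn] - psi[-nxn, -nyn])   # south-face flux
  u <- (fe + fw) / (2 * g$dy)
  v <- (gn + gs) / (2 * g$dx)
  u[g$cell_solid] <- NA_real_
  v[g$cell_solid] <- NA_real_
  div_residual <- max(abs((fe - fw) + (gn - gs))[!g$cell_solid]) / q2

  inflow <- psi[1, nyn] - psi[1, 1]
  outflow <- psi[nxn, nyn] - psi[nxn, 1]

  structure(
    list(
      geom = geom, grid = g, tfr = tfr, frr = frr, q2 = q2,
      psi = psi, omega = omega, u = u, v = v,
      u_mean = u_mean, reynolds = reynolds,
      flux_balance = abs(inflow - outflow) / inflow,
      div_residual = div_residual, linear_residual = lin_res,
      c_ref = c_ref, properties = props
    ),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "Stokes flow field: TFR %.1f mL/h (Re %.1f), %d x %d cells, flux balance %.2g\n",
    x$tfr, x$reynolds, x$grid$nx, x$grid$ny, x$flux_balance
  ))
  invisible(x)
}

inlet_fluxes <- function(flow) {
  nyn <- flow$grid$ny + 1L
  flow$psi[1, 2:nyn] - flow$psi[1, 1:(nyn - 1)]
}

# Per-cell inlet composition: organic stream (c = 1) enters along the bottom
# arm carrying a flux fraction 1 / (1 + FRR); the cell straddling the
# interface gets the fractional value so the injected species flux is exact.
inlet_composition <- function(flow, frr) {
  fin <- inlet_fluxes(flow)
  target <- flow$q2 / (1 + frr)
  cum <- cumsum(fin)
  c_in <- numeric(length(fin))
  below <- cum <= target
  c_in[below] <- 1
  k <- which(!below)[1]
  if (!is.na(k)) {
    prev <- if (k > 1) cum[k - 1] else 0
    c_in[k] <- (target - prev) / fin[k]
  }
  c_in
}

#' Solve steady species transport on a flow field
#'
#' Advection-diffusion of the normalised ethanol mass fraction `c` (1 on the
#' organic inlet arm, 0 on the aqueous arm) through the channel, using the
#' velocity field of [solve_flow()]. Convection is discretised with
#' first-order upwinding plus, by default, a deferred-correction van Leer
#' (TVD) higher-order term iterated to a fixed point: the upwind operator
#' keeps the solution bounded while the correction removes most of the
#' streamwise numerical diffusion that plain upwinding would add. With
#' `coupling = "sequential"` the diffusivity is evaluated once at the
#' reference composition; with `coupling = "picard"` the
#' concentration-dependent diffusivity is iterated as well. An explicit
#' non-convergence error (with the residual history attached) is raised at
#' the iteration cap.
#'
#' @param flow a `flow_field`.
#' @param properties a [property_model()].
#' @param frr flow rate ratio; defaults to the one stored in the flow field.
#' @param coupling property coupling mode.
#' @param scheme convection scheme: `"vanleer"` (deferred-correction TVD,
#'   default) or `"upwind"` (first order, direct solve).
#' @param tol fixed-point tolerance: largest concentration change between
#'   sweeps (concentrations are order one).
#' @param max_iter iteration cap for the deferred correction / Picard loop.
#' @param relax under-relaxation factor on the deferred-correction update,
#'   damping limiter cycling.
#' @return An object of class `transport_field` with the cell concentration
#'   matrix (`NA` in solid cells), the inlet composition, a species-balance
#'   relative error and solver metadata.
#' @export
solve_transport <- function(flow, properties = property_model(), frr = flow$frr,
                            coupling = c("sequential", "picard"),
                            scheme = c("vanleer", "upwind"),
                            tol = 1e-5, max_iter = 200, relax = 0.8) {
  stopifnot(inherits(flow, "flow_field"))
  coupling <- match.arg(coupling)
  scheme <- match.arg(scheme)
  g <- flow$grid
  if (!is.numeric(frr) || frr <= 0) stop_invalid("'frr' must be positive")

  fluid <- !g$cell_solid
  cid <- matrix(NA_integer_, g$nx, g$ny)
  cid[fluid] <- seq_len(sum(fluid))
  nc <- sum(fluid)

  nyn <- g$ny + 1L; nxn <- g$nx + 1L
  psi <- flow$psi
  fe <- psi[-1, -1] - psi[-1, -nyn]
  fw <- psi[-nxn, -1] - psi[-nxn, -nyn]
  gn <- -(psi[-1, -1] - psi[-nxn, -1])
  c_in <- inlet_composition(flow, frr)
  fin <- inlet_fluxes(flow)

  c_ref <- 1 / (1 + frr)
  d_cell <- matrix(mixture_properties(properties, c_ref)$diffusivity,
                   g$nx, g$ny)

  assemble <- function(d_cell) {
    idx <- which(fluid, arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    rowp <- cid[idx]
    aPP <- numeric(nc)
    b <- numeric(nc)
    ti <- tj <- tv <- list()
    add <- function(r, c, v) {
      ti[[length(ti) + 1L]] <<- r; tj[[length(tj) + 1L]] <<- c
      tv[[length(tv) + 1L]] <<- v
    }
    harm <- function(a, b) 2 * a * b / (a + b)

    # east faces (to cell i+1): interior fluid-fluid faces
    has_e <- i < g$nx
    ne <- cbind(pmin(i + 1L, g$nx), j)
    open_e <- has_e & fluid[ne]
    Fo <- fe[idx]                       # outward (east) flux
    dif <- harm(d_cell[idx], d_cell[ne]) * g$dy / g$dx
    sel <- open_e
    aPP[rowp[sel]] <- aPP[rowp[sel]] + pmax(Fo[sel], 0) + dif[sel]
    add(rowp[sel], cid[ne][sel], pmin(Fo[sel], 0) - dif[sel])
    # outlet east face (convective outflow only)
    sel <- i == g$nx
    aPP[rowp[sel]] <- aPP[rowp[sel]] + pmax(Fo[sel], 0)

    # west faces
    has_w <- i > 1
    nw <- cbind(pmax(i - 1L, 1L), j)
    open_w <- has_w & fluid[nw]
    Fo <- -fw[idx]                      # outward (west) flux
    dif <- harm(d_cell[idx], d_cell[nw]) * g$dy / g$dx
    sel <- open_w
    aPP[rowp[sel]] <- aPP[rowp[sel]] + pmax(Fo[sel], 0) + dif[sel]
    add(rowp[sel], cid[nw][sel], pmin(Fo[sel], 0) - dif[sel])
    # inlet west face: inflow carries c_in (convective only)
    sel <- i == 1
    b[rowp[sel]] <- b[rowp[sel]] + fin[j[sel]] * c_in[j[sel]]
    aPP[rowp[sel]] <- aPP[rowp[sel]] + pmax(Fo[sel], 0) # guard reversed flow

    # north faces
    has_n <- j < g$ny
    nn <- cbind(i, pmin(j + 1L, g$ny))
    open_n <- has_n & fluid[nn]
    Fo <- gn[idx]
    dif <- harm(d_cell[idx], d_cell[nn]) * g$dx / g$dy
    sel <- open_n
    aPP[rowp[sel]] <- aPP[rowp[sel]] + pmax(Fo[sel], 0) + dif[sel]
    add(rowp[sel], cid[nn][sel], pmin(Fo[sel], 0) - dif[sel])

    # south faces
    has_s <- j > 1
    ns <- cbind(i, pmax(j - 1L, 1L))
    open_s <- has_s & fluid[ns]
    Fo <- -gn[cbind(i, pmax(j - 1L, 1L))]
    Fo[!has_s] <- 0
    dif <- harm(d_cell[idx], d_cell[ns]) * g$dx / g$dy
    sel <- open_s
    aPP[rowp[sel]] <- aPP[rowp[sel]] + pmax(Fo[sel], 0) + dif[sel]
    add(rowp[sel], cid[ns][sel], pmin(Fo[sel], 0) - dif[sel])

    add(seq_len(nc), seq_len(nc), aPP)
    A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tv),
                              dims = c(nc, nc))
    list(A = A, b = b)
  }

  # deferred-correction face lists: interior fluid-fluid faces with their
  # upwind, downwind and second-upwind cells (the latter NA when cut off by a
  # wall or boundary, in which case the face stays first-order upwind)
  face_tables <- local({
    cell_at <- function(i, j) {
      ok <- i >= 1 & i <= g$nx & j >= 1 & j <= g$ny
      out <- rep(NA_integer_, length(i))
      out[ok] <- cid[cbind(i[ok], j[ok])]
      out
    }
    ew <- which(fluid[-g$nx, , drop = FALSE] &
                  fluid[-1, , drop = FALSE], arr.ind = TRUE)
    eF <- fe[cbind(ew[, 1], ew[, 2])]
    epos <- eF >= 0
    eU <- ifelse(epos, cell_at(ew[, 1], ew[, 2]), cell_at(ew[, 1] + 1L, ew[, 2]))
    eD <- ifelse(epos, cell_at(ew[, 1] + 1L, ew[, 2]), cell_at(ew[, 1], ew[, 2]))
    eUU <- ifelse(epos, cell_at(ew[, 1] - 1L, ew[, 2]),
                  cell_at(ew[, 1] + 2L, ew[, 2]))
    ns <- which(fluid[, -g$ny, drop = FALSE] &
                  fluid[, -1, drop = FALSE], arr.ind = TRUE)
    nF <- gn[cbind(ns[, 1], ns[, 2])]
    npos <- nF >= 0
    nU <- ifelse(npos, cell_at(ns[, 1], ns[, 2]), cell_at(ns[, 1], ns[, 2] + 1L))
    nD <- ifelse(npos, cell_at(ns[, 1], ns[, 2] + 1L), cell_at(ns[, 1], ns[, 2]))
    nUU <- ifelse(npos, cell_at(ns[, 1], ns[, 2] - 1L),
                  cell_at(ns[, 1], ns[, 2] + 2L))
    list(
      flux = c(eF, nF), U = c(eU, nU), D = c(eD, nD), UU = c(eUU, nUU),
      # rows receiving -corr (cell owning the outward flux) and +corr
      row_out = c(ifelse(epos, eU, eD), ifelse(npos, nU, nD)),
      row_in = c(ifelse(epos, eD, eU), ifelse(npos, nD, nU))
    )
  })

  ho_correction <- function(cvec) {
    ft <- face_tables
    cU <- cvec[ft$U]
    cD <- cvec[ft$D]
    dcd <- cD - cU
    r <- rep(0, length(dcd))
    okUU <- !is.na(ft$UU) & abs(dcd) > 1e-12
    r[okUU] <- (cU[okUU] - cvec[ft$UU[okUU]]) / dcd[okUU]
    phi <- (r + abs(r)) / (1 + abs(r))    # van Leer limiter
    corr <- abs(ft$flux) * 0.5 * phi * dcd
    # the extra face flux |F| * 0.5 * phi * (cD - cU) leaves the upwind cell
    # and enters the downwind cell; moved to the right-hand side it appears
    # with opposite signs
    db <- numeric(nc)
    s_out <- rowsum(corr, ft$row_out, reorder = FALSE)
    db[as.integer(rownames(s_out))] <- db[as.integer(rownames(s_out))] - s_out
    s_in <- rowsum(corr, ft$row_in, reorder = FALSE)
    db[as.integer(rownames(s_in))] <- db[as.integer(rownames(s_in))] + s_in
    db
  }

  history <- numeric(0)
  iterations <- 0L
  nonconv <- function(what, delta) {
    stop(errorCondition(
      paste0(what, " did not converge in ", max_iter,
             " iterations (last change ", signif(delta, 3), ")"),
      class = c("pdmix_nonconvergence", "error"),
      history = history
    ))
  }

  solve_for_d <- function(d_cell, c_start = NULL) {
    sys <- assemble(d_cell)
    fac <- Matrix::lu(sys$A)
    cvec <- as.numeric(Matrix::solve(fac, sys$b))
    iterations <<- iterations + 1L
    if (scheme == "vanleer") {
      repeat {
        cnew <- as.numeric(Matrix::solve(fac, sys$b + ho_correction(cvec)))
        cnew <- relax * cnew + (1 - relax) * cvec
        delta <- max(abs(cnew - cvec)) / relax
        history <<- c(history, delta)
        cvec <- cnew
        iterations <<- iterations + 1L
        if (delta < tol) break
        if (iterations >= max_iter) nonconv("deferred-correction sweep", delta)
      }
    }
    cvec
  }

  cvec <- solve_for_d(d_cell)
  if (coupling == "picard") {
    repeat {
      cmatv <- matrix(c_ref, g$nx, g$ny)
      cmatv[fluid] <- pmin(pmax(cvec, 0), 1)
      d_cell <- matrix(
        mixture_properties(properties, as.numeric(cmatv))$diffusivity,
        g$nx, g$ny
      )
      cnew <- solve_for_d(d_cell)
      delta <- max(abs(cnew - cvec))
      history <- c(history, delta)
      cvec <- cnew
      if (delta < tol) break
      if (iterations >= max_iter) nonconv("Picard property coupling", delta)
    }
  }

  cmat <- matrix(NA_real_, g$nx, g$ny)
  cmat[fluid] <- cvec
  species_in <- sum(fin * c_in)
  out_flux <- fe[g$nx, ]
  species_out <- sum(pmax(out_flux, 0) * ifelse(fluid[g$nx, ], cmat[g$nx, ], 0))
  balance <- abs(species_in - species_out) / species_in

  structure(
    list(
      flow = flow, grid = g, frr = frr, c = cmat, c_in = c_in,
      species_balance = balance, coupling = coupling, scheme = scheme,
      iterations = iterations, history = history,
      overshoot = max(0, max(cvec) - 1, -min(cvec)),
      d_ref = mixture_properties(properties, c_ref)$diffusivity
    ),
    class = "transport_field"
  )
}

#' @export
print.transport_field <- function(x, ...) {
  cat(sprintf(
    "Transport field: FRR %.1f, species balance %.2g, c in [%.3f, %.3f] (%s, %s coupling)\n",
    x$frr, x$species_balance, min(x$c, na.rm = TRUE), max(x$c, na.rm = TRUE),
    x$scheme, x$coupling
  ))
  invisible(x)
}

#' Transient two-stream diffusion across the channel width
#'
#' One-dimensional transverse diffusion of an initially segregated two-stream
#' profile in a closed channel, integrated by Crank-Nicolson time stepping on
#' the same finite-volume diffusion operator used by [solve_transport()].
#' Used to validate the transport machinery against the classical
#' Fourier-series solution.
#'
#' @param width channel width (m).
#' @param diffusivity constant diffusivity (m2/s).
#' @param split organic stream fraction: initial `c = 1` for `y < split *
#'   width`, else 0.
#' @param time physical time (s).
#' @param ny cells across the width.
#' @param n_steps time steps.
#' @return Data frame with cell-centre `y` and concentration `c`.
#' @export
transient_diffusion_profile <- function(width, diffusivity, split, time,
                                        ny = 80, n_steps = 400) {
  if (split <= 0 || split >= 1) stop_invalid("'split' must be in (0, 1)")
  dy <- width / ny
  y <- (seq_len(ny) - 0.5) * dy
  c0 <- pmin(pmax((split * width - (y - dy / 2)) / dy, 0), 1)
  L <- matrix(0, ny, ny)
  for (j in seq_len(ny)) {
    if (j > 1) { L[j, j - 1] <- 1; L[j, j] <- L[j, j] - 1 }
    if (j < ny) { L[j, j + 1] <- 1; L[j, j] <- L[j, j] - 1 }
  }
  L <- L * diffusivity / dy^2
  dt <- time / n_steps
  M1 <- diag(ny) - dt / 2 * L
  M2 <- diag(ny) + dt / 2 * L
  step <- solve(M1, M2)
  cc <- c0
  for (s in seq_len(n_steps)) cc <- step %*% cc
  data.frame(y = y, c = as.numeric(cc))
}
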