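# Serial-section integration: fused Gromov-Wasserstein optimal transport
# between the topic profiles and intra-slide distance structures of two
# slides, closed-form weighted Procrustes (SVD) recovery of the rigid
# transform implied by a coupling, and sequential stacking of an ordered
# slide series into one 3D frame.
#
# The linear OT subproblems are solved exactly with a transportation simplex
# (lexicographic perturbation for degeneracy, flows recomputed on the optimal
# basis tree with the unperturbed marginals), so returned couplings are
# vertices of the transportation polytope with marginals exact to machine
# precision.

#' Exact discrete optimal transport (transportation simplex)
#'
#' Minimizes `sum(cost * P)` over couplings `P >= 0` with row sums `p` and
#' column sums `q` (`sum(p) == sum(q)`).
#'
#' @param cost n x m cost matrix.
#' @param p,q Marginal weight vectors (default uniform).
#' @return Optimal coupling matrix, same shape as `cost`.
#' @export
ot_exact <- function(cost, p = NULL, q = NULL) {
  n <- nrow(cost)
  m <- ncol(cost)
  p <- p %||% rep(1 / n, n)
  q <- q %||% rep(1 / m, m)
  if (abs(sum(p) - sum(q)) > 1e-9) stop("marginals must have equal mass")
  # lexicographic-style perturbation removes degeneracy
  delta <- min(c(p, q)) * 1e-7 / (n + 1)
  pp <- p + delta * seq_len(n)
  qq <- q
  qq[m] <- qq[m] + delta * n * (n + 1) / 2

  # Northwest-corner initial basic feasible solution
  basis_i <- integer(0)
  basis_j <- integer(0)
  flow <- numeric(0)
  supply <- pp
  demand <- qq
  i <- 1L
  j <- 1L
  while (i <= n && j <= m) {
    f <- min(supply[i], demand[j])
    basis_i <- c(basis_i, i)
    basis_j <- c(basis_j, j)
    flow <- c(flow, f)
    supply[i] <- supply[i] - f
    demand[j] <- demand[j] - f
    if (supply[i] <= demand[j]) i <- i + 1L else j <- j + 1L
  }
  stopifnot(length(flow) == n + m - 1L)

  tree_potentials <- function(bi, bj, cost) {
    u <- rep(NA_real_, n)
    v <- rep(NA_real_, m)
    u[1] <- 0
    # adjacency over basic arcs
    repeat {
      changed <- FALSE
      for (a in seq_along(bi)) {
        if (!is.na(u[bi[a]]) && is.na(v[bj[a]])) {
          v[bj[a]] <- cost[bi[a], bj[a]] - u[bi[a]]
          changed <- TRUE
        } else if (is.na(u[bi[a]]) && !is.na(v[bj[a]])) {
          u[bi[a]] <- cost[bi[a], bj[a]] - v[bj[a]]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    list(u = u, v = v)
  }

  find_cycle <- function(bi, bj, ei, ej) {
    # path in the basis tree from column node ej back to row node ei;
    # nodes: rows 1..n, cols n+1..n+m
    adj <- vector("list", n + m)
    for (a in seq_along(bi)) {
      r <- bi[a]
      cnode <- n + bj[a]
      adj[[r]] <- c(adj[[r]], a)
      adj[[cnode]] <- c(adj[[cnode]], a)
    }
    # BFS from ei (row node) to n+ej (column node)
    target <- n + ej
    prev_arc <- rep(NA_integer_, n + m)
    prev_node <- rep(NA_integer_, n + m)
    visited <- rep(FALSE, n + m)
    queue <- ei
    visited[ei] <- TRUE
    while (length(queue)) {
      node <- queue[1]
      queue <- queue[-1]
      if (node == target) break
      for (a in adj[[node]]) {
        other <- if (node <= n) n + bj[a] else bi[a]
        if (!visited[other]) {
          visited[other] <- TRUE
          prev_arc[other] <- a
          prev_node[other] <- node
          queue <- c(queue, other)
        }
      }
    }
    # walk back: arcs on the tree path
    path <- integer(0)
    node <- target
    while (node != ei) {
      path <- c(prev_arc[node], path)
      node <- prev_node[node]
    }
    path
  }

  max_pivots <- 50L * (n + m)
  for (iter in seq_len(max_pivots)) {
    pot <- tree_potentials(basis_i, basis_j, cost)
    rc <- cost - outer(pot$u, rep(1, m)) - outer(rep(1, n), pot$v)
    rc[cbind(basis_i, basis_j)] <- 0
    ent <- which.min(rc)
    if (rc[ent] >= -1e-11) break
    ei <- row(cost)[ent]
    ej <- col(cost)[ent]
    path <- find_cycle(basis_i, basis_j, ei, ej)
    # entering arc has +, alternate along the path starting from ei
    signs <- numeric(length(path))
    node <- ei
    for (s in seq_along(path)) {
      a <- path[s]
      if (basis_i[a] == node) {
        signs[s] <- -1  # leaves row node -> arc flow decreases
        node <- n + basis_j[a]
      } else {
        signs[s] <- +1
        node <- basis_i[a]
      }
    }
    neg <- path[signs < 0]
    theta <- min(flow[neg])
    leave <- neg[which.min(flow[neg])]
    flow[path] <- flow[path] + signs * theta
    basis_i[leave] <- ei
    basis_j[leave] <- ej
    flow[leave] <- theta
  }

  # Recompute flows on the optimal basis tree with the unperturbed marginals
  flow_exact <- numeric(length(basis_i))
  deg_r <- tabulate(basis_i, n)
  deg_c <- tabulate(basis_j, m)
  rs <- p
  cs <- q
  active <- rep(TRUE, length(basis_i))
  for (step in seq_along(basis_i)) {
    leafs <- which(active & (deg_r[basis_i] == 1L | deg_c[basis_j] == 1L))
    a <- leafs[1]
    i <- basis_i[a]
    j <- basis_j[a]
    f <- if (deg_r[i] == 1L) rs[i] else cs[j]
    flow_exact[a] <- f
    rs[i] <- rs[i] - f
    cs[j] <- cs[j] - f
    deg_r[i] <- deg_r[i] - 1L
    deg_c[j] <- deg_c[j] - 1L
    active[a] <- FALSE
  }
  P <- matrix(0, n, m)
  P[cbind(basis_i, basis_j)] <- pmax(flow_exact, 0)
  P
}

#' Construct a slide layer
#'
#' Bundles one slide's per-spot topic profiles, coordinates and intra-slide
#' Euclidean distance matrix for alignment.
#'
#' @param topics Topics x spots matrix (columns sum to 1), e.g. from
#'   [predict.celltopic_model()] (`$topics`).
#' @param coords Coordinate table (`spot_id`, `x`, `y`) covering the spots,
#'   or a 2 x n / n x 2 numeric matrix in spot order.
#' @param id Slide identifier.
#' @param z_index Section order index (integer).
#' @param celltype Optional per-spot dominant cell-type labels carried into
#'   the 3D output.
#' @return Object of class `slide_layer` with `X` (topics), `Z` (2 x n
#'   coordinates), `D` (n x n distances), `id`, `z_index`.
#' @export
slide_layer <- function(topics, coords, id = "layer", z_index = 1L,
                        celltype = NULL) {
  X <- as_dense(topics)
  if (is.data.frame(coords)) {
    Z <- t(coords_matrix(coords, colnames(X)))
  } else {
    Z <- as_dense(coords)
    if (nrow(Z) != 2L) Z <- t(Z)
    stopifnot(nrow(Z) == 2L, ncol(Z) == ncol(X))
  }
  if (max(abs(colSums(X) - 1)) > 1e-6) {
    stop("topic columns must sum to 1")
  }
  D <- as.matrix(stats::dist(t(Z)))
  structure(list(X = X, Z = Z, D = D, id = id, z_index = as.integer(z_index),
                 celltype = celltype),
            class = "slide_layer")
}

#' @export
print.slide_layer <- function(x, ...) {
  cat("Slide layer '", x$id, "': ", ncol(x$X), " spots, ", nrow(x$X),
      " topics, z-index ", x$z_index, "\n", sep = "")
  invisible(x)
}

topic_cost <- function(X, Xp, cost = c("sqeuclidean", "cosine", "kl")) {
  cost <- match.arg(cost)
  if (cost == "sqeuclidean") {
    n2a <- colSums(X^2)
    n2b <- colSums(Xp^2)
    pmax(outer(n2a, n2b, "+") - 2 * crossprod(X, Xp), 0)
  } else if (cost == "cosine") {
    na <- sqrt(colSums(X^2))
    nb <- sqrt(colSums(Xp^2))
    1 - crossprod(X, Xp) / outer(na, nb)
  } else {
    eps <- 1e-10
    Xs <- X + eps
    Xps <- Xp + eps
    # KL(x_i || x'_j) = sum_k x_ki log x_ki - sum_k x_ki log x'_kj
    ent <- colSums(Xs * log(Xs))
    outer(ent, rep(1, ncol(Xp))) - crossprod(Xs, log(Xps))
  }
}

fgw_cost_value <- function(Pi, C, D, Dp, lambda, p, q) {
  constC <- outer(as.vector((D^2) %*% p), rep(1, length(q))) +
    outer(rep(1, length(p)), as.vector((Dp^2) %*% q))
  gw <- sum((constC - 2 * D %*% Pi %*% Dp) * Pi)
  (1 - lambda) * sum(C * Pi) + lambda * gw
}

#' Align two slide layers by fused Gromov-Wasserstein transport
#'
#' Finds a coupling `Pi` with uniform marginals minimizing
#' `(1 - lambda) * sum c(X_i, X'_j) Pi_ij +
#'  lambda * sum (D_ik - D'_jl)^2 Pi_ij Pi_kl`,
#' trading per-spot topic dissimilarity against preservation of intra-slide
#' spot distances. `lambda = 0` reduces to a linear OT problem on the topic
#' cost alone. Solved by conditional-gradient iterations whose linear
#' subproblems use the exact transportation simplex; the step size comes from
#' an exact quadratic line search.
#'
#' @param a,b `slide_layer` objects sharing the topic space.
#' @param lambda Structure weight in `[0, 1]` (default 0.1).
#' @param cost Topic dissimilarity: `"sqeuclidean"` (default), `"cosine"`,
#'   or `"kl"`.
#' @param max_iter Conditional-gradient iteration cap.
#' @param tol Relative improvement tolerance.
#' @return Object of class `layer_mapping`: `Pi` (n x n' coupling), achieved
#'   cost `value`, `lambda`, `iterations`, `converged`.
#' @export
pairwise_align <- function(a, b, lambda = 0.1,
                           cost = c("sqeuclidean", "cosine", "kl"),
                           max_iter = 100, tol = 1e-9) {
  stopifnot(inherits(a, "slide_layer"), inherits(b, "slide_layer"))
  if (nrow(a$X) != nrow(b$X)) stop("layers have different topic spaces")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  cost <- match.arg(cost)
  C <- topic_cost(a$X, b$X, cost)
  n <- ncol(a$X)
  m <- ncol(b$X)
  p <- rep(1 / n, n)
  q <- rep(1 / m, m)
  D <- a$D
  Dp <- b$D
  Fv <- function(Pi) fgw_cost_value(Pi, C, D, Dp, lambda, p, q)
  constC <- outer(as.vector((D^2) %*% p), rep(1, m)) +
    outer(rep(1, n), as.vector((Dp^2) %*% q))
  Pi <- outer(p, q)
  f_cur <- Fv(Pi)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    grad <- (1 - lambda) * C +
      2 * lambda * (constC - 2 * D %*% Pi %*% Dp)
    Pi_lp <- ot_exact(grad, p, q)
    Delta <- Pi_lp - Pi
    if (sum(grad * Delta) >= -1e-12) { converged <- TRUE; break }
    # exact line search on the quadratic t -> F(Pi + t Delta), t in [0, 1]
    f0 <- f_cur
    f1 <- Fv(Pi + Delta)
    fh <- Fv(Pi + 0.5 * Delta)
    aa <- 2 * (f1 + f0 - 2 * fh)
    bb <- f1 - f0 - aa
    t_star <- if (aa > 1e-18) max(0, min(1, -bb / (2 * aa)))
              else if (f1 <= f0) 1 else 0
    if (t_star == 0) { converged <- TRUE; break }
    Pi <- Pi + t_star * Delta
    f_new <- Fv(Pi)
    if (f_cur - f_new < tol * max(1, abs(f_cur))) {
      f_cur <- f_new
      converged <- TRUE
      break
    }
    f_cur <- f_new
  }
  if (!converged) {
    warning("conditional gradient did not converge in ", max_iter,
            " iterations; returning the best iterate")
  }
  structure(list(Pi = Pi, value = f_cur, lambda = lambda, cost = cost,
                 iterations = it, converged = converged,
                 from = a$id, to = b$id),
            class = "layer_mapping")
}

#' @export
print.layer_mapping <- function(x, ...) {
  cat("Layer mapping ", x$from, " -> ", x$to, ": ", nrow(x$Pi), " x ",
      ncol(x$Pi), " coupling, F = ", signif(x$value, 6),
      " (lambda = ", x$lambda, ", ", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Weighted Procrustes rigid transform from a coupling
#'
#' Closed-form SVD solution of
#' `min_{R, v} sum_ij Pi_ij || Za_i - R Zb_j - v ||^2` over proper rotations
#' (`det(R) = +1`; reflections are never returned): both coordinate sets are
#' centered at their coupling-weighted means, the 2 x 2 cross-covariance
#' `H = Za_c Pi Zb_c'` is decomposed as `H = U S V'`, and
#' `R = U diag(1, det(U V')) V'`, `v = mu_a - R mu_b`.
#'
#' @param Z_a,Z_b 2 x n and 2 x n' coordinate matrices.
#' @param Pi n x n' non-negative coupling.
#' @return List of class `rigid_transform` with rotation `R` (2 x 2) and
#'   translation `v` (length 2), mapping `b` coordinates into `a`'s frame
#'   as `R %*% Z_b + v`.
#' @export
procrustes_pair <- function(Z_a, Z_b, Pi) {
  Z_a <- as_dense(Z_a)
  Z_b <- as_dense(Z_b)
  stopifnot(nrow(Z_a) == 2L, nrow(Z_b) == 2L,
            ncol(Z_a) == nrow(Pi), ncol(Z_b) == ncol(Pi))
  s <- sum(Pi)
  mu_a <- as.vector(Z_a %*% rowSums(Pi)) / s
  mu_b <- as.vector(Z_b %*% colSums(Pi)) / s
  Za <- Z_a - mu_a
  Zb <- Z_b - mu_b
  H <- Za %*% Pi %*% t(Zb)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate weighted covariance; cannot recover a rotation ",
         "(coupling mass concentrated on too few spots)")
  }
  d <- det(sv$u %*% t(sv$v))
  R <- sv$u %*% diag(c(1, sign(d))) %*% t(sv$v)
  v <- mu_a - as.vector(R %*% mu_b)
  structure(list(R = R, v = v), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- atan2(x$R[2, 1], x$R[1, 1]) * 180 / pi
  cat("Rigid transform: rotation ", signif(ang, 5), " deg, translation (",
      signif(x$v[1], 5), ", ", signif(x$v[2], 5), ")\n", sep = "")
  invisible(x)
}

#' Stack an ordered slide series into one 3D frame
#'
#' Sequentially aligns each pair of adjacent layers with
#' [pairwise_align()], recovers the rigid transform with
#' [procrustes_pair()], accumulates the transforms so every layer is
#' expressed in the first layer's frame, and assigns each layer the height
#' `z_index * z_spacing`.
#'
#' @param layers Ordered list of `slide_layer` objects (section order).
#' @param lambda,cost Passed to [pairwise_align()].
#' @param z_spacing Section thickness in array units per z-index step.
#' @return List with `coordinates` (`data.frame`: spot_id, slide, x, y, z,
#'   and `celltype` when layers carry it) and `mappings` (list of
#'   `layer_mapping`).
#' @export
stack_layers <- function(layers, lambda = 0.1, cost = "sqeuclidean",
                         z_spacing = 1) {
  stopifnot(length(layers) >= 2L)
  lapply(layers, function(l) stopifnot(inherits(l, "slide_layer")))
  mappings <- vector("list", length(layers) - 1L)
  Zt <- vector("list", length(layers))
  Zt[[1]] <- layers[[1]]$Z
  for (k in seq_len(length(layers) - 1L)) {
    map <- tryCatch(
      pairwise_align(layers[[k]], layers[[k + 1]], lambda = lambda,
                     cost = cost),
      error = function(e) {
        stop("alignment of layers '", layers[[k]]$id, "' and '",
             layers[[k + 1]]$id, "' failed: ", conditionMessage(e))
      })
    mappings[[k]] <- map
    tr <- procrustes_pair(Zt[[k]], layers[[k + 1]]$Z, map$Pi)
    Zt[[k + 1]] <- tr$R %*% layers[[k + 1]]$Z + tr$v
  }
  coords <- do.call(rbind, lapply(seq_along(layers), function(k) {
    l <- layers[[k]]
    out <- data.frame(spot_id = colnames(l$X) %||%
                        paste0(l$id, "_", seq_len(ncol(l$X))),
                      slide = l$id,
                      x = Zt[[k]][1, ], y = Zt[[k]][2, ],
                      z = l$z_index * z_spacing,
                      stringsAsFactors = FALSE)
    if (!is.null(l$celltype)) out$celltype <- l$celltype
    out
  }))
  list(coordinates = coords, mappings = mappings)
}
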