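#' Multi-trait additive REML (unstructured covariances)
#'
#' Fits `y_t = mu_t + u_t + e_t` jointly over traits with
#' `u ~ N(0, G0 (x) K)` and `e ~ N(0, R0 (x) I)`, `G0` and `R0`
#' unstructured trait covariance matrices estimated by EM-REML on the
#' mixed-model equations. Per-trait missing values are allowed: each
#' individual contributes the traits it has (residual blocks are taken on
#' the observed subset; covariance updates are trait-pairwise, which is
#' exact EM for complete data).
#'
#' @param Y numeric matrix, individuals x traits (rownames = ids, NA
#'   allowed), at least 2 traits.
#' @param K relationship matrix covering all ids of `Y`.
#' @param max_iter,tol EM iteration cap and relative convergence tolerance.
#' @param engine `"auto"` (eigen-decoupled fast path for complete data,
#'   general mixed-model-equation path otherwise), or force one of
#'   `"complete"` / `"general"`.
#' @return object of class `"popgs_mtfit"`: `G0`, `R0`, `genetic_cor`,
#'   `logLik`, `aic`, `fixef`, `blup` (list of per-trait GEBV vectors over
#'   all K ids), `converged`, `iterations`, `bent` (TRUE when a covariance
#'   update had to be bent back to positive definite).
#' @export
fit_multitrait <- function(Y, K, max_iter = 200, tol = 1e-6,
                           engine = c("auto", "complete", "general")) {
  engine <- match.arg(engine)
  Y <- as.matrix(Y)
  t_n <- ncol(Y)
  if (t_n < 2) stop("need at least 2 traits")
  if (is.null(rownames(Y))) stop("Y must carry ids as rownames")
  ids_all <- rownames(K)
  if (length(setdiff(rownames(Y), ids_all))) {
    stop("phenotyped ids absent from K")
  }
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(t_n))
  if (engine == "complete" && anyNA(Y)) {
    stop("engine 'complete' requires a complete trait matrix")
  }
  if (engine != "general" && !anyNA(Y)) {
    # complete data: the model block-diagonalizes in the eigenbasis of K
    return(mt_em_complete(Y, K, max_iter = max_iter, tol = tol))
  }
  traits <- colnames(Y)
  q <- length(ids_all)
  Kinv <- tryCatch(chol2inv(chol(K)), error = function(e) {
    stop("K is not positive definite; apply regularize() first")
  })
  logdetK <- as.numeric(determinant(K)$modulus)

  # stack observations trait-major
  obs <- which(!is.na(Y), arr.ind = TRUE)
  obs <- obs[order(obs[, 2], obs[, 1]), , drop = FALSE]
  y <- Y[obs]
  N <- length(y)
  tr_of <- obs[, 2]                      # trait index per record
  id_of <- match(rownames(Y)[obs[, 1]], ids_all)
  ind_of <- obs[, 1]
  p <- t_n                                # one intercept per trait
  # W = [X | Z], X: trait intercepts, Z: u stacked trait-major (q per trait)
  Xj <- tr_of
  Zj <- p + (tr_of - 1L) * q + id_of
  W <- Matrix::sparseMatrix(i = rep(seq_len(N), 2), j = c(Xj, Zj), x = 1,
                            dims = c(N, p + t_n * q))
  ublk <- lapply(seq_len(t_n), function(t) p + (t - 1L) * q + seq_len(q))

  # per-individual observed-trait sets (residual blocks couple them)
  obs_by_ind <- split(seq_len(N), ind_of)
  pat_of <- vapply(obs_by_ind, function(ix) {
    paste(sort(tr_of[ix]), collapse = ",")
  }, character(1))

  vy <- apply(Y, 2, stats::var, na.rm = TRUE)
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  S <- bend_pd(S)
  G0 <- S / 2
  R0 <- S / 2
  bent <- FALSE

  build_rinv <- function(R0) {
    # sparse R^{-1} over stacked records
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (pat in unique(pat_of)) {
      inds <- obs_by_ind[pat_of == pat]
      ts <- as.integer(strsplit(pat, ",")[[1]])
      Ri <- solve(R0[ts, ts, drop = FALSE])
      for (a in seq_along(ts)) for (b in seq_along(ts)) {
        ra <- vapply(inds, function(ix) ix[match(ts[a], tr_of[ix])], integer(1))
        rb <- vapply(inds, function(ix) ix[match(ts[b], tr_of[ix])], integer(1))
        ii <- c(ii, ra); jj <- c(jj, rb); xx <- c(xx, rep(Ri[a, b], length(ra)))
      }
    }
    list(Rinv = Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N)),
         logdetR = sum(vapply(unique(pat_of), function(pat) {
           ts <- as.integer(strsplit(pat, ",")[[1]])
           sum(pat_of == pat) *
             as.numeric(determinant(R0[ts, ts, drop = FALSE])$modulus)
         }, numeric(1))))
  }

  eval_state <- function(G0, R0) {
    rv <- build_rinv(R0)
    WtRW <- as.matrix(Matrix::crossprod(W, rv$Rinv %*% W))
    WtRy <- as.numeric(Matrix::crossprod(W, rv$Rinv %*% y))
    G0inv <- solve(G0)
    Cs <- WtRW
    Cs[-seq_len(p), -seq_len(p)] <- Cs[-seq_len(p), -seq_len(p)] +
      kronecker(G0inv, Kinv)
    ch <- chol(Cs)
    theta <- backsolve(ch, forwardsolve(t(ch), WtRy))
    Cinv <- chol2inv(ch)
    ypy <- sum(y * as.numeric(rv$Rinv %*% y)) - sum(theta * WtRy)
    logdetG <- q * as.numeric(determinant(G0)$modulus) + t_n * logdetK
    neg2l <- rv$logdetR + logdetG + 2 * sum(log(diag(ch))) + ypy +
      (N - p) * log(2 * pi)
    list(theta = theta, Cinv = Cinv, neg2l = neg2l)
  }

  vech <- function(S) S[lower.tri(S, diag = TRUE)]
  unvech <- function(v) {
    S <- matrix(0, t_n, t_n)
    S[lower.tri(S, diag = TRUE)] <- v
    S + t(S) - diag(diag(S))
  }
  converged <- FALSE
  st <- eval_state(G0, R0)
  iter <- 0L
  par_hist <- list(c(vech(G0), vech(R0)))
  while (iter < max_iter) {
    iter <- iter + 1L
    theta <- st$theta
    Cinv <- st$Cinv
    # genetic covariance update
    G0n <- matrix(0, t_n, t_n)
    for (a in seq_len(t_n)) for (b in a:t_n) {
      ua <- theta[ublk[[a]]]
      ub <- theta[ublk[[b]]]
      tr <- sum(Kinv * Cinv[ublk[[a]], ublk[[b]]])
      G0n[a, b] <- G0n[b, a] <- (sum(ua * (Kinv %*% ub)) + tr) / q
    }
    # residual covariance update, trait-pairwise over shared individuals
    ehat <- y - as.numeric(W %*% theta)
    R0n <- matrix(0, t_n, t_n)
    for (a in seq_len(t_n)) for (b in a:t_n) {
      acc <- 0
      nab <- 0L
      for (ix in obs_by_ind) {
        ia <- ix[match(a, tr_of[ix])]
        ib <- ix[match(b, tr_of[ix])]
        if (is.na(ia) || is.na(ib)) next
        wa <- c(a, p + (a - 1L) * q + id_of[ia])
        wb <- c(b, p + (b - 1L) * q + id_of[ib])
        acc <- acc + ehat[ia] * ehat[ib] + sum(Cinv[wa, wb])
        nab <- nab + 1L
      }
      R0n[a, b] <- R0n[b, a] <- acc / max(nab, 1L)
    }
    chk <- bend_pd(G0n, floor = 1e-8 * mean(vy))
    if (!isTRUE(all.equal(chk, G0n))) bent <- TRUE
    G0n <- chk
    chk <- bend_pd(R0n, floor = 1e-8 * mean(vy))
    if (!isTRUE(all.equal(chk, R0n))) bent <- TRUE
    R0n <- chk
    # guarded Aitken acceleration on the stacked covariance parameters
    if (iter %% 6L == 0L && length(par_hist) >= 2L) {
      p2 <- c(vech(G0n), vech(R0n))
      p1 <- par_hist[[length(par_hist)]]
      p0 <- par_hist[[length(par_hist) - 1L]]
      dd <- (p2 - p1) - (p1 - p0)
      acc <- ifelse(abs(dd) > 1e-12, p1 - (p2 - p1)^2 / dd, p2)
      nh <- length(acc) / 2
      Ga <- bend_pd(unvech(acc[seq_len(nh)]), floor = 1e-8 * mean(vy))
      Ra <- bend_pd(unvech(acc[nh + seq_len(nh)]), floor = 1e-8 * mean(vy))
      st_acc <- tryCatch(eval_state(Ga, Ra), error = function(e) NULL)
      if (!is.null(st_acc)) {
        st_cur <- tryCatch(eval_state(G0n, R0n), error = function(e) NULL)
        if (!is.null(st_cur) && st_acc$neg2l < st_cur$neg2l) {
          G0n <- Ga
          R0n <- Ra
        }
      }
    }
    par_hist[[length(par_hist) + 1L]] <- c(vech(G0n), vech(R0n))
    if (length(par_hist) > 3L) par_hist <- par_hist[-1L]
    st_new <- eval_state(G0n, R0n)
    dl <- abs(st_new$neg2l - st$neg2l) / (abs(st$neg2l) + 1e-12)
    dv <- max(abs(c(G0n - G0, R0n - R0))) / (max(abs(c(G0, R0))) + 1e-12)
    G0 <- G0n
    R0 <- R0n
    st <- st_new
    if (dl < tol && dv < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("multi-trait EM-REML did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  dimnames(G0) <- dimnames(R0) <- list(traits, traits)
  gc <- stats::cov2cor(G0)
  theta <- st$theta
  blup <- lapply(seq_len(t_n), function(t) {
    stats::setNames(theta[ublk[[t]]], ids_all)
  })
  names(blup) <- traits
  k_par <- t_n * (t_n + 1)  # two unstructured t x t covariance matrices
  boundary <- any(abs(gc[lower.tri(gc)]) > 0.999) ||
    min(eigen(gc, symmetric = TRUE, only.values = TRUE)$values) < 1e-4
  out <- list(G0 = G0, R0 = R0, genetic_cor = gc,
              logLik = -0.5 * st$neg2l, aic = st$neg2l + 2 * k_par,
              fixef = stats::setNames(theta[seq_len(p)], traits),
              blup = blup, converged = converged, iterations = iter,
              bent = bent || boundary, n = nrow(Y), df = k_par)
  class(out) <- "popgs_mtfit"
  out
}

# ---- complete-data multi-trait EM in the eigenbasis of K -----------------
# With no missing cells and one record per individual, rotating each
# trait's genetic effects by the eigenvectors of K_phph turns the MME into
# independent t x t blocks per eigenvalue (bordered by the t intercepts),
# making each EM iteration O(n t^3).
mt_em_complete <- function(Y, K, max_iter = 200, tol = 1e-6) {
  t_n <- ncol(Y)
  traits <- colnames(Y)
  ids_all <- rownames(K)
  ph <- rownames(Y)
  Kp <- K[ph, ph]
  ed <- eigen(Kp, symmetric = TRUE)
  d <- pmax(ed$values, 1e-10)
  U <- ed$vectors
  n <- length(ph)
  q <- n
  Yt <- crossprod(U, Y)              # rotated records, n x t
  s <- drop(crossprod(U, rep(1, n))) # rotated intercept column
  csY <- colSums(Y)
  YtY <- crossprod(Y)
  logdetK <- sum(log(d))

  vy <- apply(Y, 2, stats::var)
  S0 <- bend_pd(stats::cov(Y))
  G0 <- S0 / 2
  R0 <- S0 / 2
  bent <- FALSE

  state <- function(G0, R0) {
    R0i <- solve(R0)
    G0i <- solve(G0)
    Binv <- array(0, c(t_n, t_n, n))
    logdetB <- 0
    for (i in seq_len(n)) {
      Bi <- R0i + G0i / d[i]
      cB <- chol(Bi)
      logdetB <- logdetB + 2 * sum(log(diag(cB)))
      Binv[, , i] <- chol2inv(cB)
    }
    # Schur complement of the t intercepts
    Sb <- n * R0i
    rb <- R0i %*% csY
    for (i in seq_len(n)) {
      RBiR <- R0i %*% Binv[, , i] %*% R0i
      Sb <- Sb - s[i]^2 * RBiR
      rb <- rb - s[i] * R0i %*% Binv[, , i] %*% (R0i %*% Yt[i, ])
    }
    Sbi <- solve(Sb)
    beta <- drop(Sbi %*% rb)
    V <- matrix(0, n, t_n)  # rotated genetic solutions v_i
    for (i in seq_len(n)) {
      V[i, ] <- drop(Binv[, , i] %*% (R0i %*% (Yt[i, ] - s[i] * beta)))
    }
    # restricted likelihood: y'Py = y'Rinv y - theta' rhs, with
    # rhs_beta = R0i csY and rhs_v_i = R0i Yt[i,]
    ypy <- sum(R0i * YtY) - sum(beta * (R0i %*% csY)) -
      sum(vapply(seq_len(n), function(i) {
        sum(V[i, ] * (R0i %*% Yt[i, ]))
      }, numeric(1)))
    neg2l <- n * as.numeric(determinant(R0)$modulus) +
      q * as.numeric(determinant(G0)$modulus) + t_n * logdetK +
      logdetB + as.numeric(determinant(Sb)$modulus) + ypy +
      (n * t_n - t_n) * log(2 * pi)
    list(beta = beta, V = V, Binv = Binv, Sbi = Sbi, R0i = R0i,
         neg2l = neg2l)
  }

  update <- function(st) {
    R0i <- st$R0i
    V <- st$V
    # posterior covariance pieces: Cvv(i,i) and border sums
    G0n <- matrix(0, t_n, t_n)
    trUU <- matrix(0, t_n, t_n)   # sum_i Cvv(i,i)
    sumCbv <- matrix(0, t_n, t_n) # sum_i s_i C^{beta v_i}
    for (i in seq_len(n)) {
      Bi <- st$Binv[, , i]
      BR <- Bi %*% R0i
      Ci <- Bi + s[i]^2 * BR %*% st$Sbi %*% t(BR)
      G0n <- G0n + (tcrossprod(V[i, ]) + Ci) / d[i]
      trUU <- trUU + Ci
      sumCbv <- sumCbv - s[i]^2 * st$Sbi %*% t(BR)
    }
    G0n <- G0n / q
    # residual update from original-coordinate residuals
    E <- Y - rep(1, n) %o% st$beta - U %*% V
    R0n <- (crossprod(E) + n * st$Sbi + sumCbv + t(sumCbv) + trUU) / n
    list(G0 = (G0n + t(G0n)) / 2, R0 = (R0n + t(R0n)) / 2)
  }

  vech <- function(S) S[lower.tri(S, diag = TRUE)]
  unvech <- function(v) {
    S <- matrix(0, t_n, t_n)
    S[lower.tri(S, diag = TRUE)] <- v
    S + t(S) - diag(diag(S))
  }
  st <- state(G0, R0)
  par_hist <- list(c(vech(G0), vech(R0)))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    up <- update(st)
    G0n <- bend_pd(up$G0, floor = 1e-8 * mean(vy))
    R0n <- bend_pd(up$R0, floor = 1e-8 * mean(vy))
    if (max(abs(G0n - up$G0)) > 1e-12 || max(abs(R0n - up$R0)) > 1e-12) {
      bent <- TRUE
    }
    if (iter %% 6L == 0L && length(par_hist) >= 2L) {
      p2 <- c(vech(G0n), vech(R0n))
      p1 <- par_hist[[length(par_hist)]]
      p0 <- par_hist[[length(par_hist) - 1L]]
      dd <- (p2 - p1) - (p1 - p0)
      acc <- ifelse(abs(dd) > 1e-12, p1 - (p2 - p1)^2 / dd, p2)
      nh <- length(acc) / 2
      Ga <- bend_pd(unvech(acc[seq_len(nh)]), floor = 1e-8 * mean(vy))
      Ra <- bend_pd(unvech(acc[nh + seq_len(nh)]), floor = 1e-8 * mean(vy))
      st_acc <- tryCatch(state(Ga, Ra), error = function(e) NULL)
      st_cur <- tryCatch(state(G0n, R0n), error = function(e) NULL)
      if (!is.null(st_acc) && !is.null(st_cur) &&
          st_acc$neg2l < st_cur$neg2l) {
        G0n <- Ga
        R0n <- Ra
      }
    }
    par_hist[[length(par_hist) + 1L]] <- c(vech(G0n), vech(R0n))
    if (length(par_hist) > 3L) par_hist <- par_hist[-1L]
    st_new <- state(G0n, R0n)
    dl <- abs(st_new$neg2l - st$neg2l) / (abs(st$neg2l) + 1e-12)
    dv <- max(abs(c(G0n - G0, R0n - R0))) / (max(abs(c(G0, R0))) + 1e-12)
    G0 <- G0n
    R0 <- R0n
    st <- st_new
    if (dl < tol && dv < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("multi-trait EM-REML did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  dimnames(G0) <- dimnames(R0) <- list(traits, traits)
  gc <- stats::cov2cor(G0)
  u_ph <- U %*% st$V                       # per-trait BLUPs, phenotyped ids
  rownames(u_ph) <- ph
  blup <- lapply(seq_len(t_n), function(tj) {
    v <- stats::setNames(rep(0, length(ids_all)), ids_all)
    v[ph] <- u_ph[, tj]
    un <- setdiff(ids_all, ph)
    if (length(un)) {
      v[un] <- drop(K[un, ph, drop = FALSE] %*%
                      solve(Kp, u_ph[, tj, drop = FALSE]))
    }
    v
  })
  names(blup) <- traits
  k_par <- t_n * (t_n + 1)
  boundary <- any(abs(gc[lower.tri(gc)]) > 0.999) ||
    min(eigen(gc, symmetric = TRUE, only.values = TRUE)$values) < 1e-4
  out <- list(G0 = G0, R0 = R0, genetic_cor = gc,
              logLik = -0.5 * st$neg2l, aic = st$neg2l + 2 * k_par,
              fixef = stats::setNames(st$beta, traits),
              blup = blup, converged = converged, iterations = iter,
              bent = bent || boundary, n = nrow(Y), df = k_par)
  class(out) <- "popgs_mtfit"
  out
}

# bend a symmetric matrix to positive definite by flooring eigenvalues
bend_pd <- function(S, floor = NULL) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (is.null(floor)) floor <- 1e-8 * max(abs(e$values), 1e-12)
  if (min(e$values) >= floor) return(S)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  dimnames(out) <- dimnames(S)
  (out + t(out)) / 2
}

#' @export
print.popgs_mtfit <- function(x, ...) {
  cat(sprintf("<popgs_mtfit> %d traits, n = %d, %s%s\n", ncol(x$G0), x$n,
              if (x$converged) sprintf("converged in %d iterations", x$iterations)
              else "NOT converged",
              if (x$bent) " [covariance bent to PD]" else ""))
  cat("genetic correlations:\n")
  print(round(x$genetic_cor, 3))
  invisible(x)
}
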