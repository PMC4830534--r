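# Henderson mixed-model equations and EM-REML for the four GBLUP variants.
#
# Model (per trait i): y_i = X_i beta_i + Z_i alpha_i + Z_i delta_i + e_i,
# X_i an intercept column, Z_i an identity (or row-deleted identity when
# phenotype records are missing). Random effects are stacked trait-major
# (all individuals of trait 1, then trait 2, ...) with priors
# alpha ~ N(0, V_alpha (x) A) and delta ~ N(0, V_delta (x) D); residuals
# e ~ N(0, V_e (x) I). Additive-only variants drop the delta term;
# univariate variants analyse each trait separately.
#
# Two algebraically identical fitting paths are provided. The "direct"
# path builds and inverts the full MME coefficient matrix (the classical
# presentation, feasible for small problems and used as a cross-check).
# The "reduced" path works with the marginal covariance
# V = V_alpha (x) A + V_delta (x) D + V_e (x) I and the projection matrix
# P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1, using the identities
# C^{uu} = G - G P G and W C^-1 W' = R - R P R to collapse every EM trace
# into t x t matrix algebra with a single (n t x n t) inverse per
# iteration.

MODEL_VARIANTS <- c("UV-A", "UV-AD", "MV-A", "MV-AD")

#' Model specification for a GBLUP variant
#'
#' @param variant One of `"UV-A"`, `"UV-AD"`, `"MV-A"`, `"MV-AD"`:
#'   univariate/multivariate, additive-only or additive + dominance.
#' @param traits Ordered character vector of trait names (exactly one for
#'   UV variants, at least two for MV variants).
#' @return A list of class `"model_spec"` with `variant`, `traits`,
#'   `multivariate` and `include_dominance`.
#' @export
model_spec <- function(variant, traits) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  multivariate <- startsWith(variant, "MV")
  if (!multivariate && length(traits) != 1L) {
    abort("Univariate variants carry exactly one trait.")
  }
  if (multivariate && length(traits) < 2L) {
    abort("Multivariate variants need at least two traits.")
  }
  structure(
    list(
      variant = variant, traits = traits, multivariate = multivariate,
      include_dominance = endsWith(variant, "AD")
    ),
    class = "model_spec"
  )
}

# ---------------------------------------------------------------------------
# Direct MME construction

solve_vc <- function(v, label) {
  out <- tryCatch(solve(v), error = function(e) NULL)
  if (is.null(out)) {
    abort(sprintf(
      "%s is singular; restart the fit from a ridged initial value (e.g. add a small constant to its diagonal).",
      label
    ))
  }
  out
}

# Blockwise inverse of R = Cov(e) for records grouped by individual;
# Z rows must be unit selection rows.
residual_inverse <- function(ind_of_record, trait_of_record, V_e) {
  N <- length(ind_of_record)
  Rinv <- matrix(0, N, N)
  for (k in unique(ind_of_record)) {
    rec <- which(ind_of_record == k)
    s <- trait_of_record[rec]
    Rinv[rec, rec] <- solve_vc(V_e[s, s, drop = FALSE], "V_e")
  }
  Rinv
}

#' Build Henderson's mixed-model equations
#'
#' Assembles the coefficient matrix and right-hand side for the (possibly
#' multi-trait) GBLUP model with additive and optional dominance terms.
#' Random-effect levels always span all individuals of the kinship
#' matrices, even when phenotype records are missing, so BLUPs of
#' unphenotyped individuals are predicted.
#'
#' @param y List of per-trait phenotype vectors (records in individual
#'   order of each `Z` block).
#' @param X List of per-trait fixed-effect incidence matrices (intercept
#'   columns).
#' @param Z List of per-trait random-effect incidence matrices; each row
#'   must be a unit selection row mapping a record to an individual.
#' @param A_inv Inverse additive relationship matrix.
#' @param D_inv Inverse dominance relationship matrix, or `NULL` for
#'   additive-only models.
#' @param vc List with `V_alpha`, `V_e` and (if `D_inv` is given)
#'   `V_delta`: trait x trait covariance components.
#' @return Object of class `"gblup_mme"`: coefficient matrix `C`, `rhs`,
#'   index `blocks`, stacked data and design (`y`, `W`), and bookkeeping.
#' @export
build_mme <- function(y, X, Z, A_inv, D_inv = NULL, vc) {
  if (!is.list(y)) y <- list(y)
  if (!is.list(X)) X <- list(X)
  if (!is.list(Z)) Z <- list(Z)
  tt <- length(y)
  n <- ncol(Z[[1L]])
  dominance <- !is.null(D_inv)
  V_alpha <- as.matrix(vc$V_alpha)
  V_e <- as.matrix(vc$V_e)
  if (dominance && is.null(vc$V_delta)) {
    abort("`vc$V_delta` is required when `D_inv` is supplied.")
  }

  Xb <- block_diag(X)
  Zb <- block_diag(Z)
  yv <- unlist(y, use.names = FALSE)
  N <- length(yv)

  # record bookkeeping from the selection rows of Z
  trait_of_record <- rep(seq_len(tt), vapply(y, length, integer(1)))
  ind_of_record <- unlist(lapply(Z, function(z) {
    idx <- apply(z != 0, 1L, which)
    if (is.list(idx) || any(abs(z[cbind(seq_len(nrow(z)), as.integer(idx))] - 1) > 1e-12)) {
      abort("Each row of `Z` must be a unit selection row.")
    }
    as.integer(idx)
  }), use.names = FALSE)

  Rinv <- residual_inverse(ind_of_record, trait_of_record, V_e)

  Ga_inv <- kronecker(solve_vc(V_alpha, "V_alpha"), A_inv)
  XtR <- crossprod(Xb, Rinv)
  ZtR <- crossprod(Zb, Rinv)
  C11 <- XtR %*% Xb
  C12 <- XtR %*% Zb
  C22 <- ZtR %*% Zb

  p <- ncol(Xb)
  nt <- n * tt
  if (dominance) {
    Gd_inv <- kronecker(solve_vc(as.matrix(vc$V_delta), "V_delta"), D_inv)
    C <- rbind(
      cbind(C11, C12, C12),
      cbind(t(C12), C22 + Ga_inv, C22),
      cbind(t(C12), C22, C22 + Gd_inv)
    )
    rhs <- c(XtR %*% yv, ZtR %*% yv, ZtR %*% yv)
    blocks <- list(
      beta = seq_len(p),
      alpha = p + seq_len(nt),
      delta = p + nt + seq_len(nt)
    )
    W <- cbind(Xb, Zb, Zb)
  } else {
    C <- rbind(
      cbind(C11, C12),
      cbind(t(C12), C22 + Ga_inv)
    )
    rhs <- c(XtR %*% yv, ZtR %*% yv)
    blocks <- list(beta = seq_len(p), alpha = p + seq_len(nt), delta = NULL)
    W <- cbind(Xb, Zb)
  }
  structure(
    list(
      C = symmetrize(C), rhs = as.numeric(rhs), blocks = blocks,
      n = n, n_traits = tt, y = yv, W = W,
      trait_of_record = trait_of_record, ind_of_record = ind_of_record,
      dominance = dominance
    ),
    class = "gblup_mme"
  )
}

#' Solve Henderson's mixed-model equations by direct inversion
#'
#' @param mme A `"gblup_mme"` from [build_mme()], or a coefficient matrix
#'   (then `rhs` must be given and only `solutions`/`C_inv` are returned).
#' @param rhs Right-hand side when `mme` is a bare matrix.
#' @return List with `beta`, `alpha_hat` (individuals x traits),
#'   `delta_hat`, the full inverse `C_inv` (needed by the EM traces),
#'   `solutions` and residuals `e`.
#' @export
solve_mme <- function(mme, rhs = NULL) {
  if (is.matrix(mme)) {
    mme <- list(C = mme, rhs = rhs, blocks = NULL)
  }
  ch <- tryCatch(chol(mme$C), error = function(e) {
    abort("The MME coefficient matrix is numerically singular.")
  })
  C_inv <- chol2inv(ch)
  sol <- as.numeric(C_inv %*% mme$rhs)
  out <- list(solutions = sol, C_inv = C_inv)
  if (!is.null(mme$blocks)) {
    n <- mme$n
    tt <- mme$n_traits
    out$beta <- sol[mme$blocks$beta]
    out$alpha_hat <- matrix(sol[mme$blocks$alpha], n, tt)
    out$delta_hat <- if (mme$dominance) {
      matrix(sol[mme$blocks$delta], n, tt)
    } else {
      matrix(0, n, tt)
    }
    out$e <- mme$y - as.numeric(mme$W %*% sol)
  }
  out
}

#' EM-REML update for a genetic (co)variance component
#'
#' One expectation-maximisation update of the additive or dominance trait
#' (co)variance for a trait pair:
#' \deqn{\tilde\sigma_{ij} = [u_i' K^{-1} u_j + tr(K^{-1} C^{ij})] / t}
#' where `u` are the current BLUPs, `K` the relationship matrix of the
#' term, `C^{ij}` the (trait i, trait j) sub-block of the inverse MME
#' coefficient matrix for that term, and `t` the number of random-effect
#' levels.
#'
#' @param u_i,u_j BLUP vectors of the two traits for this random term.
#' @param K_inv Inverse relationship matrix (`A^-1` or `D^-1`).
#' @param C_block_inv The (i, j) sub-block of the inverse coefficient
#'   matrix for this term.
#' @param t_levels Number of random-effect levels (individuals).
#' @return The scalar updated (co)variance.
#' @export
em_update_genetic <- function(u_i, u_j, K_inv, C_block_inv, t_levels) {
  if (t_levels <= 0) {
    abort("`t_levels` must be positive.")
  }
  quad <- as.numeric(crossprod(u_i, K_inv %*% u_j))
  tr <- sum(K_inv * t(C_block_inv))
  (quad + tr) / t_levels
}

#' EM-REML update for a residual (co)variance component
#'
#' \deqn{\tilde\sigma_{e,ij} = \{e_i' e_j + tr([W C^{-1} W']_{ij})\} / n}
#' with `W = [X, Z, Z]` the column-concatenated design and `n` the number
#' of records of the trait pair.
#'
#' @param e_i,e_j Residual vectors of the two traits (same record
#'   support).
#' @param W_i,W_j Rows of the stacked design matrix for the records of
#'   each trait.
#' @param C_inv Full inverse MME coefficient matrix.
#' @param n_levels Number of records.
#' @return The scalar updated residual (co)variance.
#' @export
em_update_residual <- function(e_i, W_i, C_inv, n_levels,
                               e_j = e_i, W_j = W_i) {
  if (length(e_i) != length(e_j) || nrow(W_i) != nrow(W_j)) {
    abort("Trait record blocks must have matching dimensions.")
  }
  if (n_levels <= 0) {
    abort("`n_levels` must be positive.")
  }
  tr <- sum((W_i %*% C_inv) * W_j)
  (sum(e_i * e_j) + tr) / n_levels
}

# ---------------------------------------------------------------------------
# REML log-likelihood (common to both paths), computed on observed records.

reml_loglik_pieces <- function(V, yv, n_blocks_per_trait) {
  ch <- chol(V)
  Vi <- chol2inv(ch)
  logdetV <- 2 * sum(log(diag(ch)))
  tt <- length(n_blocks_per_trait)
  offs <- c(0L, cumsum(n_blocks_per_trait))
  ViX <- matrix(0, nrow(V), tt)
  for (k in seq_len(tt)) {
    cols <- (offs[k] + 1L):offs[k + 1L]
    ViX[, k] <- rowSums(Vi[, cols, drop = FALSE])
  }
  XtViX <- matrix(0, tt, tt)
  for (k in seq_len(tt)) {
    rows <- (offs[k] + 1L):offs[k + 1L]
    XtViX[k, ] <- colSums(ViX[rows, , drop = FALSE])
  }
  Qx <- solve(XtViX)
  Viy <- as.numeric(Vi %*% yv)
  Xty <- vapply(seq_len(tt), function(k) {
    sum(Viy[(offs[k] + 1L):offs[k + 1L]])
  }, numeric(1))
  beta <- as.numeric(Qx %*% Xty)
  Py <- Viy - as.numeric(ViX %*% (Qx %*% Xty))
  P <- Vi - ViX %*% tcrossprod(Qx, ViX)
  ll <- -0.5 * (logdetV + as.numeric(determinant(XtViX)$modulus) + sum(yv * Py))
  list(Vi = Vi, P = P, Py = Py, beta = beta, Qx = Qx, loglik = ll)
}

# T[k, l] = tr(P^{kl} M) for the t x t grid of n x n blocks of P;
# M = NULL means the identity.
block_trace <- function(P, M, no, tt) {
  out <- matrix(0, tt, tt)
  for (k in seq_len(tt)) {
    bk <- trait_block(k, no)
    for (l in seq_len(tt)) {
      bl <- trait_block(l, no)
      out[k, l] <- if (is.null(M)) {
        sum(P[cbind(bk, bl)])
      } else {
        sum(P[bk, bl] * M)
      }
    }
  }
  out
}

clip_psd <- function(v, label, flag_env) {
  eg <- eigen(symmetrize(v), symmetric = TRUE)
  if (min(eg$values) < 0) {
    flag_env$projected <- TRUE
    vals <- pmax(eg$values, 0)
    v <- eg$vectors %*% (vals * t(eg$vectors))
    v <- symmetrize(v)
  }
  v
}

default_init_vc <- function(Y, dominance) {
  Yc <- Y[stats::complete.cases(Y), , drop = FALSE]
  Vp <- if (nrow(Yc) >= 3L) {
    cov(Yc)
  } else {
    cov(Y, use = "pairwise.complete.obs")
  }
  Vp <- as.matrix(Vp)
  Vp[is.na(Vp)] <- 0
  eg <- eigen(symmetrize(Vp), symmetric = TRUE)
  floor_ev <- max(eg$values) * 1e-6
  if (min(eg$values) < floor_ev) {
    Vp <- eg$vectors %*% (pmax(eg$values, floor_ev) * t(eg$vectors))
    Vp <- symmetrize(Vp)
  }
  k <- if (dominance) 3 else 2
  list(
    V_alpha = Vp / k,
    V_delta = if (dominance) Vp / k else NULL,
    V_e = Vp / k
  )
}

rel_change <- function(new, old, scale0) {
  max(abs(new - old) / pmax(abs(old), 1e-8 * scale0))
}

# ---------------------------------------------------------------------------
# Reduced-path EM-REML (whole-individual missingness only).

em_reml_reduced <- function(Y, A, D, dominance, init, tol, max_iter) {
  n <- nrow(Y)
  tt <- ncol(Y)
  obs <- which(stats::complete.cases(Y))
  no <- length(obs)
  if (no < 3L) {
    abort("Too few fully observed individuals to fit the model.")
  }
  Yo <- Y[obs, , drop = FALSE]
  Au <- unclass(A)
  Ao <- Au[obs, obs, drop = FALSE]
  Du <- if (dominance) unclass(D) else NULL
  Do <- if (dominance) Du[obs, obs, drop = FALSE] else NULL
  yv <- as.numeric(Yo)

  Va <- as.matrix(init$V_alpha)
  Vd <- if (dominance) as.matrix(init$V_delta) else NULL
  Ve <- as.matrix(init$V_e)
  scale0 <- mean(diag(Ve)) + mean(diag(Va))
  flag <- new.env()
  flag$projected <- FALSE

  trace <- vector("list", max_iter)
  converged <- FALSE
  it <- 0L

  if (tt == 1L) {
    # scalar case: drop the Kronecker machinery entirely
    y1 <- Yo[, 1L]
    va <- Va[1L, 1L]
    vd <- if (dominance) Vd[1L, 1L] else 0
    ve <- Ve[1L, 1L]
    ones <- rep(1, no)
    pass <- NULL
    scalar_pass <- function(va, vd, ve) {
      V <- va * Ao + diag(ve, no)
      if (dominance) V <- V + vd * Do
      ch <- chol(V)
      Vi <- chol2inv(ch)
      vix <- rowSums(Vi)
      xtvix <- sum(vix)
      beta <- sum(vix * y1) / xtvix
      r <- y1 - beta
      e <- Vi %*% r
      ll <- -0.5 * (2 * sum(log(diag(ch))) + log(xtvix) + sum(r * e))
      list(beta = beta, e = as.numeric(e), ll = ll, Vi = Vi, vix = vix,
           xtvix = xtvix)
    }
    while (it < max_iter) {
      it <- it + 1L
      pass <- scalar_pass(va, vd, ve)
      e <- pass$e
      # traces of P against Ao, Do and I without forming P twice
      PA <- sum(pass$Vi * Ao) - sum(pass$vix * (Ao %*% pass$vix)) / pass$xtvix
      Pd <- if (dominance) {
        sum(pass$Vi * Do) - sum(pass$vix * (Do %*% pass$vix)) / pass$xtvix
      } else 0
      Pt <- sum(diag(pass$Vi)) - sum(pass$vix^2) / pass$xtvix
      Ae <- Ao %*% e
      va_new <- (va^2 * sum(e * Ae) + n * va - va^2 * PA) / n
      if (dominance) {
        De <- Do %*% e
        vd_new <- (vd^2 * sum(e * De) + n * vd - vd^2 * Pd) / n
      }
      eres <- y1 - pass$beta - va * Ae - (if (dominance) vd * De else 0)
      ve_new <- (sum(eres^2) + no * ve - ve^2 * Pt) / no
      va_new <- max(va_new, 0)
      ve_new <- max(ve_new, 0)
      if (dominance) vd_new <- max(vd_new, 0)
      delta_max <- max(
        abs(va_new - va) / max(abs(va), 1e-8 * scale0),
        if (dominance) abs(vd_new - vd) / max(abs(vd), 1e-8 * scale0) else 0,
        abs(ve_new - ve) / max(abs(ve), 1e-8 * scale0)
      )
      trace[[it]] <- c(iteration = it, loglik = pass$ll,
                       max_rel_change = delta_max)
      va <- va_new
      ve <- ve_new
      if (dominance) vd <- vd_new
      if (delta_max < tol) {
        converged <- TRUE
        break
      }
    }
    pass <- scalar_pass(va, vd, ve)
    alpha_hat <- (Au[, obs, drop = FALSE] %*% pass$e) * va
    delta_hat <- if (dominance) {
      (Du[, obs, drop = FALSE] %*% pass$e) * vd
    } else {
      matrix(0, n, 1L)
    }
    return(list(
      beta = pass$beta, alpha_hat = alpha_hat, delta_hat = delta_hat,
      vc = list(V_alpha = matrix(va, 1L, 1L),
                V_delta = if (dominance) matrix(vd, 1L, 1L) else NULL,
                V_e = matrix(ve, 1L, 1L)),
      n_iter = it, converged = converged, loglik = pass$ll,
      trace = do.call(rbind, trace[seq_len(it)]),
      vc_projected = flag$projected, method = "reduced", obs = obs
    ))
  }

  Ino <- diag(no)
  while (it < max_iter) {
    it <- it + 1L
    V <- kronecker(Va, Ao) + kronecker(Ve, Ino)
    if (dominance) V <- V + kronecker(Vd, Do)
    pieces <- reml_loglik_pieces(V, yv, rep(no, tt))
    P <- pieces$P
    E <- matrix(pieces$Py, no, tt)

    S_A <- crossprod(E, Ao %*% E)
    T_A <- block_trace(P, Ao, no, tt)
    Va_new <- symmetrize((Va %*% S_A %*% Va + n * Va - Va %*% T_A %*% Va) / n)
    if (dominance) {
      S_D <- crossprod(E, Do %*% E)
      T_D <- block_trace(P, Do, no, tt)
      Vd_new <- symmetrize((Vd %*% S_D %*% Vd + n * Vd - Vd %*% T_D %*% Vd) / n)
    }
    alpha_o <- Ao %*% E %*% Va
    delta_o <- if (dominance) Do %*% E %*% Vd else matrix(0, no, tt)
    Eres <- Yo - rep(1, no) %*% t(pieces$beta) - alpha_o - delta_o
    Tp <- block_trace(P, NULL, no, tt)
    Ve_new <- symmetrize((crossprod(Eres) + no * Ve - Ve %*% Tp %*% Ve) / no)

    Va_new <- clip_psd(Va_new, "V_alpha", flag)
    if (dominance) Vd_new <- clip_psd(Vd_new, "V_delta", flag)
    Ve_new <- clip_psd(Ve_new, "V_e", flag)

    delta_max <- max(
      rel_change(Va_new, Va, scale0),
      if (dominance) rel_change(Vd_new, Vd, scale0) else 0,
      rel_change(Ve_new, Ve, scale0)
    )
    trace[[it]] <- c(iteration = it, loglik = pieces$loglik,
                     max_rel_change = delta_max)
    Va <- Va_new
    Ve <- Ve_new
    if (dominance) Vd <- Vd_new
    if (delta_max < tol) {
      converged <- TRUE
      break
    }
  }

  # final solve at the converged components
  V <- kronecker(Va, Ao) + kronecker(Ve, Ino)
  if (dominance) V <- V + kronecker(Vd, Do)
  pieces <- reml_loglik_pieces(V, yv, rep(no, tt))
  E <- matrix(pieces$Py, no, tt)
  alpha_hat <- Au[, obs, drop = FALSE] %*% E %*% Va
  delta_hat <- if (dominance) {
    Du[, obs, drop = FALSE] %*% E %*% Vd
  } else {
    matrix(0, n, tt)
  }

  list(
    beta = pieces$beta, alpha_hat = alpha_hat, delta_hat = delta_hat,
    vc = list(V_alpha = Va, V_delta = Vd, V_e = Ve),
    n_iter = it, converged = converged, loglik = pieces$loglik,
    trace = do.call(rbind, trace[seq_len(it)]),
    vc_projected = flag$projected, method = "reduced", obs = obs
  )
}

# ---------------------------------------------------------------------------
# Rotated-path EM-REML for additive-only variants. With a single kinship,
# A = Q L Q' diagonalises the marginal covariance: rotating records by
# (I_t (x) Q') turns V into n independent t x t blocks
# V^(m) = L_m V_alpha + V_e, so each EM iteration costs O(n t^3) instead
# of a dense (n t)^3 inverse. Identical updates to the dense path.

em_reml_rotated <- function(Y, A, init, tol, max_iter) {
  n <- nrow(Y)
  tt <- ncol(Y)
  obs <- which(stats::complete.cases(Y))
  no <- length(obs)
  if (no < 3L) {
    abort("Too few fully observed individuals to fit the model.")
  }
  Au <- unclass(A)
  Ao <- Au[obs, obs, drop = FALSE]
  eg <- eigen(symmetrize(Ao), symmetric = TRUE)
  L <- eg$values
  Q <- eg$vectors
  Yt <- crossprod(Q, Y[obs, , drop = FALSE])  # rotated records, no x t
  xr <- as.numeric(crossprod(Q, rep(1, no)))  # rotated intercept column

  Va <- as.matrix(init$V_alpha)
  Ve <- as.matrix(init$V_e)
  scale0 <- mean(diag(Ve)) + mean(diag(Va))
  flag <- new.env()
  flag$projected <- FALSE

  trace <- vector("list", max_iter)
  converged <- FALSE
  it <- 0L

  if (tt == 1L) {
    # scalar special case: everything is vector arithmetic in the eigenbasis
    y1 <- Yt[, 1L]
    va <- Va[1L, 1L]
    ve <- Ve[1L, 1L]
    pass <- NULL
    scalar_pass <- function(va, ve) {
      d <- L * va + ve
      vi <- 1 / d
      xtvix <- sum(xr^2 * vi)
      beta <- sum(xr * vi * y1) / xtvix
      r <- y1 - xr * beta
      e <- vi * r
      ll <- -0.5 * (sum(log(d)) + log(xtvix) + sum(r * e))
      pdiag <- vi - (xr * vi)^2 / xtvix
      list(beta = beta, e = e, ll = ll, pdiag = pdiag)
    }
    while (it < max_iter) {
      it <- it + 1L
      pass <- scalar_pass(va, ve)
      va_new <- (va^2 * sum(L * pass$e^2) + n * va - va^2 * sum(L * pass$pdiag)) / n
      eres <- y1 - xr * pass$beta - (L * pass$e) * va
      ve_new <- (sum(eres^2) + no * ve - ve^2 * sum(pass$pdiag)) / no
      va_new <- max(va_new, 0)
      ve_new <- max(ve_new, 0)
      delta_max <- max(
        abs(va_new - va) / max(abs(va), 1e-8 * scale0),
        abs(ve_new - ve) / max(abs(ve), 1e-8 * scale0)
      )
      trace[[it]] <- c(iteration = it, loglik = pass$ll,
                       max_rel_change = delta_max)
      va <- va_new
      ve <- ve_new
      if (delta_max < tol) {
        converged <- TRUE
        break
      }
    }
    pass <- scalar_pass(va, ve)
    E_un <- Q %*% (pass$e)
    alpha_hat <- (Au[, obs, drop = FALSE] %*% E_un) * va
    return(list(
      beta = pass$beta, alpha_hat = alpha_hat,
      delta_hat = matrix(0, n, 1L),
      vc = list(V_alpha = matrix(va, 1L, 1L), V_delta = NULL,
                V_e = matrix(ve, 1L, 1L)),
      n_iter = it, converged = converged, loglik = pass$ll,
      trace = do.call(rbind, trace[seq_len(it)]),
      vc_projected = flag$projected, method = "rotated", obs = obs
    ))
  }

  # One pass of the rotated algebra: inverse blocks, projection blocks,
  # GLS mean and log-likelihood. P^(m) = Vi^(m) - u_m Qx u_m' with
  # u_m = Vi^(m) xr_m.
  solve_pass <- function(Va, Ve) {
    Vi <- array(0, c(tt, tt, no))
    logdetV <- 0
    for (m in seq_len(no)) {
      Vm <- L[m] * Va + Ve
      chm <- chol(Vm)
      logdetV <- logdetV + 2 * sum(log(diag(chm)))
      Vi[, , m] <- chol2inv(chm)
    }
    # rotated X: record (m, trait k) has xr[m] on intercept column k, so
    # X'V^-1X = sum_m xr[m]^2 Vi^(m) and X'V^-1 y = sum_m xr[m] Vi^(m) y_m
    XtViX <- matrix(0, tt, tt)
    Xty <- numeric(tt)
    Viy <- matrix(0, no, tt)
    for (m in seq_len(no)) {
      XtViX <- XtViX + xr[m]^2 * Vi[, , m]
      vy <- Vi[, , m] %*% Yt[m, ]
      Viy[m, ] <- vy
      Xty <- Xty + xr[m] * vy
    }
    Qx <- solve(XtViX)
    beta <- as.numeric(Qx %*% Xty)
    # Py rows: Vi^(m) (y_m - xr[m] beta)
    E <- matrix(0, no, tt)
    ypy <- 0
    for (m in seq_len(no)) {
      rm <- Yt[m, ] - xr[m] * beta
      pm <- Vi[, , m] %*% rm
      E[m, ] <- pm
      ypy <- ypy + sum(rm * pm)
    }
    ll <- -0.5 * (logdetV + as.numeric(determinant(XtViX)$modulus) + ypy)
    list(Vi = Vi, Qx = Qx, beta = beta, E = E, loglik = ll)
  }

  # T_A[k,l] = sum_m L_m P^(m)[k,l] and Tp[k,l] = sum_m P^(m)[k,l],
  # with P^(m) = Vi^(m) - xr[m]^2 Vi^(m) Qx Vi^(m).
  projection_sums <- function(pass) {
    T_A <- matrix(0, tt, tt)
    Tp <- matrix(0, tt, tt)
    for (m in seq_len(no)) {
      Vim <- pass$Vi[, , m]
      Pm <- Vim - xr[m]^2 * Vim %*% pass$Qx %*% Vim
      T_A <- T_A + L[m] * Pm
      Tp <- Tp + Pm
    }
    list(T_A = T_A, Tp = Tp)
  }

  while (it < max_iter) {
    it <- it + 1L
    pass <- solve_pass(Va, Ve)
    E <- pass$E
    S_A <- crossprod(E, L * E)
    ps <- projection_sums(pass)
    Va_new <- symmetrize((Va %*% S_A %*% Va + n * Va - Va %*% ps$T_A %*% Va) / n)
    alpha_rot <- (L * E) %*% Va
    Eres <- Yt - outer(xr, pass$beta) - alpha_rot
    Ve_new <- symmetrize((crossprod(Eres) + no * Ve - Ve %*% ps$Tp %*% Ve) / no)

    Va_new <- clip_psd(Va_new, "V_alpha", flag)
    Ve_new <- clip_psd(Ve_new, "V_e", flag)
    delta_max <- max(rel_change(Va_new, Va, scale0),
                     rel_change(Ve_new, Ve, scale0))
    trace[[it]] <- c(iteration = it, loglik = pass$loglik,
                     max_rel_change = delta_max)
    Va <- Va_new
    Ve <- Ve_new
    if (delta_max < tol) {
      converged <- TRUE
      break
    }
  }

  pass <- solve_pass(Va, Ve)
  # back-rotate: alpha_full = A[, obs] Q E Va
  E_un <- Q %*% pass$E
  alpha_hat <- Au[, obs, drop = FALSE] %*% E_un %*% Va

  list(
    beta = pass$beta, alpha_hat = alpha_hat,
    delta_hat = matrix(0, n, tt),
    vc = list(V_alpha = Va, V_delta = NULL, V_e = Ve),
    n_iter = it, converged = converged, loglik = pass$loglik,
    trace = do.call(rbind, trace[seq_len(it)]),
    vc_projected = flag$projected, method = "rotated", obs = obs
  )
}

# ---------------------------------------------------------------------------
# Direct-path EM-REML via explicit MME (small problems; per-cell missing).

em_reml_direct <- function(Y, A, D, dominance, init, tol, max_iter) {
  n <- nrow(Y)
  tt <- ncol(Y)
  obs_list <- lapply(seq_len(tt), function(k) which(!is.na(Y[, k])))
  if (any(vapply(obs_list, length, integer(1)) < 2L)) {
    abort("Each trait needs at least two phenotype records.")
  }
  Au <- unclass(A)
  A_inv <- solve(Au)
  D_inv <- if (dominance) solve(unclass(D)) else NULL
  y <- lapply(seq_len(tt), function(k) Y[obs_list[[k]], k])
  X <- lapply(obs_list, function(o) matrix(1, length(o), 1L))
  Z <- lapply(obs_list, function(o) diag(n)[o, , drop = FALSE])

  Va <- as.matrix(init$V_alpha)
  Vd <- if (dominance) as.matrix(init$V_delta) else NULL
  Ve <- as.matrix(init$V_e)
  scale0 <- mean(diag(Ve)) + mean(diag(Va))
  flag <- new.env()
  flag$projected <- FALSE

  rec_off <- c(0L, cumsum(vapply(y, length, integer(1))))
  rec_rows <- lapply(seq_len(tt), function(k) (rec_off[k] + 1L):rec_off[k + 1L])

  ll_direct <- function(vc) {
    # marginal covariance on observed records, for the monitoring criterion
    blocks <- vector("list", tt)
    V <- matrix(0, rec_off[tt + 1L], rec_off[tt + 1L])
    for (i in seq_len(tt)) {
      for (j in seq_len(tt)) {
        oi <- obs_list[[i]]
        oj <- obs_list[[j]]
        blk <- vc$V_alpha[i, j] * Au[oi, oj, drop = FALSE]
        if (dominance) blk <- blk + vc$V_delta[i, j] * unclass(D)[oi, oj, drop = FALSE]
        blk <- blk + vc$V_e[i, j] * outer(oi, oj, "==")
        V[rec_rows[[i]], rec_rows[[j]]] <- blk
      }
    }
    yv <- unlist(y, use.names = FALSE)
    reml_loglik_pieces(symmetrize(V), yv, vapply(y, length, integer(1)))$loglik
  }

  trace <- vector("list", max_iter)
  converged <- FALSE
  it <- 0L
  sol <- NULL
  while (it < max_iter) {
    it <- it + 1L
    vc <- list(V_alpha = Va, V_delta = Vd, V_e = Ve)
    mme <- build_mme(y, X, Z, A_inv, D_inv, vc)
    sol <- solve_mme(mme)

    Va_new <- matrix(0, tt, tt)
    Vd_new <- if (dominance) matrix(0, tt, tt) else NULL
    Ve_new <- matrix(0, tt, tt)
    for (i in seq_len(tt)) {
      for (j in i:tt) {
        ai <- mme$blocks$alpha[trait_block(i, n)]
        aj <- mme$blocks$alpha[trait_block(j, n)]
        Va_new[i, j] <- Va_new[j, i] <- em_update_genetic(
          sol$alpha_hat[, i], sol$alpha_hat[, j], A_inv,
          sol$C_inv[ai, aj, drop = FALSE], n
        )
        if (dominance) {
          di <- mme$blocks$delta[trait_block(i, n)]
          dj <- mme$blocks$delta[trait_block(j, n)]
          Vd_new[i, j] <- Vd_new[j, i] <- em_update_genetic(
            sol$delta_hat[, i], sol$delta_hat[, j], D_inv,
            sol$C_inv[di, dj, drop = FALSE], n
          )
        }
        shared <- intersect(obs_list[[i]], obs_list[[j]])
        ri <- rec_rows[[i]][match(shared, obs_list[[i]])]
        rj <- rec_rows[[j]][match(shared, obs_list[[j]])]
        Ve_new[i, j] <- Ve_new[j, i] <- em_update_residual(
          sol$e[ri], mme$W[ri, , drop = FALSE], sol$C_inv, length(shared),
          sol$e[rj], mme$W[rj, , drop = FALSE]
        )
      }
    }
    Va_new <- clip_psd(Va_new, "V_alpha", flag)
    if (dominance) Vd_new <- clip_psd(Vd_new, "V_delta", flag)
    Ve_new <- clip_psd(Ve_new, "V_e", flag)

    delta_max <- max(
      rel_change(Va_new, Va, scale0),
      if (dominance) rel_change(Vd_new, Vd, scale0) else 0,
      rel_change(Ve_new, Ve, scale0)
    )
    trace[[it]] <- c(
      iteration = it,
      loglik = ll_direct(list(V_alpha = Va, V_delta = Vd, V_e = Ve)),
      max_rel_change = delta_max
    )
    Va <- Va_new
    Ve <- Ve_new
    if (dominance) Vd <- Vd_new
    if (delta_max < tol) {
      converged <- TRUE
      break
    }
  }

  vc <- list(V_alpha = Va, V_delta = Vd, V_e = Ve)
  mme <- build_mme(y, X, Z, A_inv, D_inv, vc)
  sol <- solve_mme(mme)

  list(
    beta = sol$beta, alpha_hat = sol$alpha_hat, delta_hat = sol$delta_hat,
    vc = vc, n_iter = it, converged = converged,
    loglik = ll_direct(vc),
    trace = do.call(rbind, trace[seq_len(it)]),
    vc_projected = flag$projected, method = "direct",
    obs = which(rowSums(!is.na(Y)) > 0L)
  )
}

# ---------------------------------------------------------------------------

#' Fit a GBLUP model by EM-REML
#'
#' Estimates unstructured trait (co)variance components for the chosen
#' model variant by expectation-maximisation REML and returns fixed-effect
#' means and additive (and dominance) BLUPs from Henderson's mixed-model
#' equations. Univariate variants analyse each trait separately and are
#' returned as one combined fit. Individuals present in the relationship
#' matrices but with missing phenotype rows stay in the random-effect
#' levels, so their genetic values are predicted — this is the mechanism
#' behind [kfold_cv()].
#'
#' @param data Data frame / tibble of phenotypes: an id column (see
#'   `id_col`) plus one numeric column per trait; `NA` marks a missing
#'   record. Ids must appear in `rownames(A)`.
#' @param A Additive relationship matrix (positive definite; see
#'   [make_positive_definite()]).
#' @param D Dominance relationship matrix (required for `*-AD` variants).
#' @param variant Model variant, one of `"UV-A"`, `"UV-AD"`, `"MV-A"`,
#'   `"MV-AD"`.
#' @param traits Trait columns to analyse (default: all numeric non-id
#'   columns).
#' @param id_col Name or index of the id column (default first column).
#' @param init Optional initial variance components, a list with
#'   `V_alpha`, `V_e` and (for AD variants) `V_delta`; the default splits
#'   the phenotypic covariance equally among the fitted components.
#' @param tol Convergence tolerance on the maximum relative change of all
#'   variance parameters (default `1e-6`).
#' @param max_iter Maximum EM iterations (default 500).
#' @param method `"auto"` (default) picks the fastest exact path: the
#'   eigen-rotated path for additive-only variants, the reduced
#'   marginal-covariance path for additive-dominance variants, and the
#'   explicit MME path for per-cell missingness. `"rotated"`, `"reduced"`
#'   and `"direct"` force a path. All paths perform the same EM updates
#'   and give identical trajectories up to round-off.
#' @param seed Reserved for future stochastic restarts; the fit itself is
#'   deterministic.
#' @return Object of class `"gblup_fit"`; see [tidy.gblup_fit()],
#'   [glance.gblup_fit()], [predict.gblup_fit()] and `autoplot()`.
#' @export
fit_gblup <- function(data, A, D = NULL,
                      variant = c("MV-AD", "MV-A", "UV-AD", "UV-A"),
                      traits = NULL, id_col = 1L, init = NULL,
                      tol = 1e-6, max_iter = 500L,
                      method = c("auto", "rotated", "reduced", "direct"),
                      seed = NULL) {
  variant <- match.arg(variant, MODEL_VARIANTS[c(4L, 3L, 2L, 1L)])
  method <- match.arg(method)
  dominance <- endsWith(variant, "AD")
  if (dominance && is.null(D)) {
    abort("`D` is required for additive-dominance variants.")
  }

  parsed <- parse_pheno(data, A, traits, id_col)
  Y <- parsed$Y
  traits <- parsed$traits
  tt <- length(traits)
  multivariate <- startsWith(variant, "MV")

  if (!multivariate && tt > 1L) {
    # analyse each trait separately, then combine
    subfits <- lapply(traits, function(tr) {
      fit_gblup(data, A, D,
        variant = variant, traits = tr, id_col = id_col,
        init = init_subset(init, match(tr, traits)), tol = tol,
        max_iter = max_iter, method = method
      )
    })
    return(combine_uv_fits(subfits, variant, traits, A))
  }
  spec <- model_spec(variant, traits)

  if (is.null(init)) {
    init <- default_init_vc(Y, dominance)
  } else {
    init <- list(
      V_alpha = as.matrix(init$V_alpha),
      V_delta = if (dominance) as.matrix(init$V_delta) else NULL,
      V_e = as.matrix(init$V_e)
    )
  }

  whole_individual <- all(rowSums(is.na(Y)) %in% c(0L, tt))
  path <- switch(method,
    auto = if (!whole_individual) {
      "direct"
    } else if (dominance) {
      "reduced"
    } else {
      "rotated"
    },
    rotated = "rotated",
    reduced = "reduced",
    direct = "direct"
  )
  if (path %in% c("reduced", "rotated") && !whole_individual) {
    abort("This path requires whole-individual missingness; use method = \"direct\".")
  }
  if (path == "rotated" && dominance) {
    abort("The rotated path applies to additive-only variants.")
  }

  res <- switch(path,
    rotated = em_reml_rotated(Y, A, init, tol, max_iter),
    reduced = em_reml_reduced(Y, A, D, dominance, init, tol, max_iter),
    direct = em_reml_direct(Y, A, D, dominance, init, tol, max_iter)
  )

  dimnames(res$alpha_hat) <- list(rownames(A), traits)
  dimnames(res$delta_hat) <- list(rownames(A), traits)
  vc <- lapply(res$vc, function(v) {
    if (!is.null(v)) dimnames(v) <- list(traits, traits)
    v
  })
  structure(
    list(
      variant = variant, spec = spec, traits = traits, ids = rownames(A),
      beta = stats::setNames(res$beta, traits),
      alpha_hat = res$alpha_hat, delta_hat = res$delta_hat,
      vc = vc, n_iter = res$n_iter, converged = res$converged,
      loglik = res$loglik,
      trace = tibble::as_tibble(as.data.frame(res$trace)),
      vc_projected = res$vc_projected, method = res$method,
      n = nrow(Y), n_obs = length(res$obs), tol = tol
    ),
    class = "gblup_fit"
  )
}

parse_pheno <- function(data, A, traits, id_col) {
  data <- as.data.frame(data)
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) {
    abort("Duplicated ids in the phenotype table.")
  }
  id_name <- if (is.numeric(id_col)) names(data)[id_col] else id_col
  if (is.null(traits)) {
    traits <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], id_name)
  }
  if (length(traits) == 0L) {
    abort("No trait columns found.")
  }
  if (!all(ids %in% rownames(A))) {
    abort("All phenotype ids must appear in `rownames(A)`.")
  }
  Y <- matrix(NA_real_, nrow(A), length(traits),
              dimnames = list(rownames(A), traits))
  for (tr in traits) {
    Y[ids, tr] <- data[[tr]]
  }
  list(Y = Y, traits = traits)
}

init_subset <- function(init, k) {
  if (is.null(init)) {
    return(NULL)
  }
  sub <- function(v) if (is.null(v)) NULL else as.matrix(v)[k, k, drop = FALSE]
  list(V_alpha = sub(init$V_alpha), V_delta = sub(init$V_delta),
       V_e = sub(init$V_e))
}

combine_uv_fits <- function(subfits, variant, traits, A) {
  tt <- length(traits)
  pick <- function(f, what) f$vc[[what]][1L, 1L]
  mk_vc <- function(what) {
    if (is.null(subfits[[1L]]$vc[[what]])) {
      return(NULL)
    }
    diag(vapply(subfits, pick, numeric(1), what = what), tt) |>
      `dimnames<-`(list(traits, traits))
  }
  structure(
    list(
      variant = variant, spec = NULL, traits = traits, ids = rownames(A),
      beta = stats::setNames(vapply(subfits, function(f) f$beta[[1L]], numeric(1)), traits),
      alpha_hat = do.call(cbind, lapply(subfits, function(f) f$alpha_hat)) |>
        `colnames<-`(traits),
      delta_hat = do.call(cbind, lapply(subfits, function(f) f$delta_hat)) |>
        `colnames<-`(traits),
      vc = list(V_alpha = mk_vc("V_alpha"), V_delta = mk_vc("V_delta"),
                V_e = mk_vc("V_e")),
      n_iter = max(vapply(subfits, function(f) f$n_iter, integer(1))),
      converged = all(vapply(subfits, function(f) f$converged, logical(1))),
      loglik = sum(vapply(subfits, function(f) f$loglik, numeric(1))),
      trace = dplyr::bind_rows(stats::setNames(
        lapply(subfits, function(f) f$trace), traits
      ), .id = "trait"),
      vc_projected = any(vapply(subfits, function(f) f$vc_projected, logical(1))),
      method = subfits[[1L]]$method,
      n = subfits[[1L]]$n, n_obs = subfits[[1L]]$n_obs,
      tol = subfits[[1L]]$tol,
      univariate_fits = subfits
    ),
    class = "gblup_fit"
  )
}

# ---------------------------------------------------------------------------
# Methods

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "<gblup_fit> %s: %d trait(s), %d individuals (%d with records)\n",
    x$variant, length(x$traits), x$n, x$n_obs
  ))
  cat(sprintf(
    "EM-REML: %d iteration(s), %s (logLik %.3f)\n",
    x$n_iter, if (x$converged) "converged" else "NOT converged", x$loglik
  ))
  cat("\nV_alpha:\n")
  print(round(x$vc$V_alpha, 4))
  if (!is.null(x$vc$V_delta)) {
    cat("V_delta:\n")
    print(round(x$vc$V_delta, 4))
  }
  cat("V_e:\n")
  print(round(x$vc$V_e, 4))
  invisible(x)
}

#' Tidy a GBLUP fit
#'
#' @param x A `"gblup_fit"`.
#' @param what `"blup"` (per-individual genetic values), `"vc"` (variance
#'   components, long) or `"beta"` (fixed-effect means).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gblup_fit <- function(x, what = c("blup", "vc", "beta"), ...) {
  what <- match.arg(what)
  if (what == "beta") {
    return(tibble::tibble(trait = x$traits, estimate = unname(x$beta)))
  }
  if (what == "vc") {
    comp <- list(additive = x$vc$V_alpha, dominance = x$vc$V_delta,
                 residual = x$vc$V_e)
    comp <- comp[!vapply(comp, is.null, logical(1))]
    return(dplyr::bind_rows(lapply(names(comp), function(nm) {
      v <- comp[[nm]]
      idx <- which(upper.tri(v, diag = TRUE), arr.ind = TRUE)
      tibble::tibble(
        component = nm,
        trait_1 = x$traits[idx[, 1L]],
        trait_2 = x$traits[idx[, 2L]],
        estimate = v[idx]
      )
    })))
  }
  g <- x$alpha_hat + x$delta_hat
  tibble::tibble(
    id = rep(x$ids, times = length(x$traits)),
    trait = rep(x$traits, each = length(x$ids)),
    alpha = as.numeric(x$alpha_hat),
    delta = as.numeric(x$delta_hat),
    g = as.numeric(g)
  )
}

#' One-row summary of a GBLUP fit
#'
#' @param x A `"gblup_fit"`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n = x$n, n_obs = x$n_obs, n_traits = length(x$traits),
    n_iter = x$n_iter, converged = x$converged,
    loglik = x$loglik, vc_projected = x$vc_projected,
    method = x$method
  )
}

#' Predicted phenotypes and genetic values
#'
#' The prediction for an individual-trait cell is the trait mean plus the
#' total genetic BLUP, \eqn{\hat y = \hat\beta + \hat\alpha + \hat\delta}.
#'
#' @param object A `"gblup_fit"`.
#' @param ids Individuals to predict (default all).
#' @param ... Unused.
#' @return Tibble with `id`, `trait`, `alpha`, `delta`, `g` and `y_hat`.
#' @export
predict.gblup_fit <- function(object, ids = NULL, ...) {
  out <- tidy.gblup_fit(object, "blup")
  out$y_hat <- out$g + unname(object$beta[out$trait])
  if (!is.null(ids)) {
    out <- out[out$id %in% ids, , drop = FALSE]
  }
  out
}

#' @export
autoplot.gblup_fit <- function(object, ...) {
  tr <- object$trace
  if (!"trait" %in% names(tr)) {
    tr$trait <- "all"
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$loglik,
                                   colour = .data$trait)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "EM iteration", y = "REML log-likelihood",
      title = sprintf("EM-REML trajectory (%s)", object$variant),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
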