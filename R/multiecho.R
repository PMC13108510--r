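#' Fit a T2*/S0 map from multi-echo data
#'
#' Per element, the longest prefix of echoes whose temporal-mean signal
#' exceeds `rel_floor` times the first echo's temporal mean (minimum 2
#' echoes) is fit to a monoexponential decay `S0 exp(-TE/T2*)`: a log-linear
#' least-squares fit on the temporal means initialises a Gauss-Newton
#' nonlinear refinement.  T2* is clipped to [2, 500] ms.
#'
#' @param series an `echo_series` with at least 2 echoes.
#' @param rel_floor relative signal floor defining reliable echoes.
#' @param gn_iter Gauss-Newton refinement iterations.
#' @return list of class `t2star_map`: `t2star_ms`, `s0`, `n_echoes_used`.
#' @export
fit_t2star <- function(series, rel_floor = 0.03, gn_iter = 10) {
  te <- series$te_ms
  ne <- length(te)
  stop_if(ne < 2, "need at least 2 echoes")
  sbar <- apply(series$signal, c(1, 3), mean)   # element x echo
  n <- nrow(sbar)

  # adaptive echo prefix: longest run of reliable echoes, minimum 2
  ok <- sbar > rel_floor * sbar[, 1]
  n_used <- pmax(2L, apply(ok, 1, function(o) {
    bad <- which(!o)
    if (length(bad) == 0) length(o) else bad[1] - 1L
  }))

  t2 <- numeric(n)
  s0 <- numeric(n)
  for (k in sort(unique(n_used))) {
    idx <- which(n_used == k)
    tek <- te[seq_len(k)]
    y <- pmax(sbar[idx, seq_len(k), drop = FALSE], .Machine$double.eps)
    # log-linear initialiser
    X <- cbind(1, -tek)
    XtXinv <- solve(crossprod(X))
    B <- log(y) %*% X %*% t(XtXinv)           # element x 2: [log s0, r2*]
    ls0 <- B[, 1]
    r2 <- pmax(B[, 2], 1 / 500)
    a <- exp(ls0)
    # Gauss-Newton refinement of sum_e (y_e - a exp(-te r2))^2
    for (it in seq_len(gn_iter)) {
      E <- exp(-outer(r2, tek))               # element x echo
      r <- y - a * E
      # Jacobian columns: dS/da = E ; dS/dr2 = -a te E
      J11 <- rowSums(E * E)
      J12 <- rowSums(E * (-a * E * rep(tek, each = length(idx))))
      J22 <- rowSums((a * E * rep(tek, each = length(idx)))^2)
      g1 <- rowSums(r * E)
      g2 <- rowSums(r * (-a * E * rep(tek, each = length(idx))))
      det <- J11 * J22 - J12^2
      det[abs(det) < 1e-300] <- 1e-300
      da <- (J22 * g1 - J12 * g2) / det
      dr <- (J11 * g2 - J12 * g1) / det
      a <- pmax(a + da, .Machine$double.eps)
      r2 <- pmin(pmax(r2 + dr, 1 / 500), 1 / 2)
    }
    t2[idx] <- 1 / r2
    s0[idx] <- a
  }
  t2 <- pmin(pmax(t2, 2), 500)
  structure(list(t2star_ms = t2, s0 = s0, n_echoes_used = n_used),
            class = "t2star_map")
}

#' Optimal combination of multi-echo data
#'
#' Combines echoes with per-element weights proportional to
#' `TE_e exp(-TE_e / T2*)`, normalised to sum to one, prioritising echoes
#' near the local T2* (about 30 ms in gray matter).
#'
#' @param series an `echo_series`.
#' @param t2map a `t2star_map` aligned with `series`; fitted on the fly
#'   when omitted.
#' @return a single-echo `echo_series` holding the combined data.
#' @export
optimal_combine <- function(series, t2map = NULL) {
  ne <- length(series$te_ms)
  if (ne == 1) return(series)
  if (is.null(t2map)) t2map <- fit_t2star(series)
  stop_if(length(t2map$t2star_ms) != dim(series$signal)[1],
          "t2map not aligned with series")
  te <- series$te_ms
  w <- outer(1 / t2map$t2star_ms, te, function(invt2, te) te * exp(-te * invt2))
  bad <- rowSums(w) <= 0 | !is.finite(rowSums(w))
  if (any(bad)) {
    warning("degenerate combination weights at ", sum(bad),
            " element(s); using uniform weights")
    w[bad, ] <- 1
  }
  w <- w / rowSums(w)
  out <- matrix(0, dim(series$signal)[1], dim(series$signal)[2])
  for (e in seq_len(ne)) out <- out + w[, e] * series$signal[, , e]
  new_echo_series(array(out, dim = c(dim(out), 1L)),
                  te_ms = sum(colMeans(w) * te), tr_s = series$tr_s,
                  tissue = series$tissue,
                  gm_probability = series$gm_probability,
                  coords_mm = series$coords_mm, region = series$region)
}

# Design matrix with intercept; errors on rank deficiency, naming columns.
full_rank_design <- function(mixing) {
  X <- cbind(intercept = 1, mixing)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("mixing matrix is rank deficient; offending column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  X
}

#' Kappa/rho TE-dependence scores for mixing-matrix components
#'
#' For each component, echo-wise amplitudes are obtained by ordinary least
#' squares of each echo's data on the full (z-scored) mixing matrix.  Per
#' element, two one-parameter no-intercept models are fit across echoes: an
#' S0 model (`beta_e ~ a * Sbar_e`, TE-independent, artifact-like) and an
#' R2* model (`beta_e ~ b * Sbar_e * TE_e`, TE-dependent, BOLD-like), each
#' summarised by an F statistic.  Kappa (rho) is the weighted mean of the
#' R2*-model (S0-model) F over elements, weighted by the squared component
#' amplitude on the optimally combined data.  A component is accepted when
#' `kappa / rho >= ratio_threshold`.
#'
#' @param series a multi-echo `echo_series`.
#' @param mixing frame x component matrix (columns are z-scored internally).
#' @param oc_series optionally, the optimally combined series (computed on
#'   the fly when omitted).
#' @param ratio_threshold acceptance threshold on kappa/rho (default 1).
#' @param f_cap ceiling applied to per-element F statistics (guards the
#'   noise-free limit where residuals vanish).
#' @param support_frac elements whose squared component amplitude is below
#'   this fraction of the maximum are excluded from the weighted means
#'   (the vote is restricted to the component's spatial support).
#' @return data.frame with columns `kappa`, `rho`, `accepted`, one row per
#'   component.
#' @export
kappa_rho <- function(series, mixing, oc_series = NULL,
                      ratio_threshold = 1, f_cap = 1e8,
                      support_frac = 0.05) {
  mixing <- as.matrix(mixing)
  nt <- dim(series$signal)[2]
  stop_if(nrow(mixing) != nt, "mixing rows must equal frame count")
  mixing <- zscore_cols(mixing)
  X <- full_rank_design(mixing)
  ne <- length(series$te_ms)
  stop_if(ne < 2, "kappa/rho needs multi-echo data")
  n <- dim(series$signal)[1]
  nc <- ncol(mixing)
  te <- series$te_ms

  XtXinvXt <- solve(crossprod(X)) %*% t(X)
  beta <- array(0, dim = c(n, ne, nc))
  for (e in seq_len(ne)) {
    b <- XtXinvXt %*% t(series_matrix(series, e))    # (nc+1) x n
    beta[, e, ] <- t(b[-1, , drop = FALSE])
  }
  sbar <- apply(series$signal, c(1, 3), mean)        # element x echo

  if (is.null(oc_series)) oc_series <- optimal_combine(series)
  b_oc <- XtXinvXt %*% t(series_matrix(oc_series))
  w <- t(b_oc[-1, , drop = FALSE])^2                 # element x component

  one_par_F <- function(b, x) {
    # no-intercept single-regressor fit of b on x, per row; df = (1, ne - 1)
    a <- rowSums(x * b) / pmax(rowSums(x * x), 1e-300)
    sse <- rowSums((b - a * x)^2)
    sst <- rowSums(b^2)
    f <- (sst - sse) / pmax(sse / (ne - 1), sst / f_cap / (ne - 1), 1e-300)
    pmin(pmax(f, 0), f_cap)
  }

  x0 <- sbar
  x1 <- sbar * rep(te, each = n)
  out <- data.frame(kappa = numeric(nc), rho = numeric(nc),
                    accepted = logical(nc))
  for (c in seq_len(nc)) {
    b <- beta[, , c]
    dim(b) <- c(n, ne)
    f_r2 <- one_par_F(b, x1)
    f_s0 <- one_par_F(b, x0)
    wc <- w[, c]
    wc[wc < support_frac * max(wc)] <- 0
    if (sum(wc) <= 0) wc <- rep(1, n)
    out$kappa[c] <- sum(wc * f_r2) / sum(wc)
    out$rho[c] <- sum(wc * f_s0) / sum(wc)
  }
  out$accepted <- out$kappa >= ratio_threshold * out$rho
  rownames(out) <- colnames(mixing)
  out
}

#' Rejected component indices from kappa/rho scores
#'
#' @param scores data.frame from [kappa_rho()] (needs column `accepted`).
#' @return ascending unique integer indices of rejected components.
#' @export
meica_select <- function(scores) {
  stop_if(nrow(scores) == 0, "scores must be nonempty")
  sort(unique(which(!scores$accepted)))
}
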