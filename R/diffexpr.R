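# Negative-binomial statistical core: Cox-Reid adjusted-profile-likelihood
# dispersion estimation with empirical-Bayes shrinkage, likelihood-ratio
# contrast tests with and without a fold-change threshold, BH FDR, and the
# leading-log-fold-change MDS.

DISPERSION_FLOOR <- 1e-8

# ---- internal NB fitting -----------------------------------------------------

# Vectorized one-parameter Fisher scoring for a one-way group layout:
# mu_ij = exp(offset_j + beta_{group(j)}). Groups are independent given the
# layout, so each (gene, group) mean is a scalar root-finding problem solved
# simultaneously across genes. Returns genes x groups matrix of natural-log
# coefficients.
.nb_fit_groups <- function(y, offsets, groups, phi, extra_offset = NULL,
                           maxit = 50, tol = 1e-10) {
  groups <- as.factor(groups)
  levs <- levels(groups)
  n <- nrow(y)
  beta <- matrix(0, n, length(levs), dimnames = list(rownames(y), levs))
  o <- offsets
  if (!is.null(extra_offset)) o <- o + extra_offset
  for (g in seq_along(levs)) {
    J <- which(groups == levs[g])
    yJ <- y[, J, drop = FALSE]
    eo <- exp(o[J])
    b <- log((rowSums(yJ) + 0.5) / sum(eo))
    for (it in seq_len(maxit)) {
      mu <- exp(b) %o% eo
      denom <- 1 + phi * mu
      score <- rowSums((yJ - mu) / denom)
      info <- rowSums(mu / denom)
      step <- score / pmax(info, 1e-12)
      step <- pmin(pmax(step, -5), 5)
      b <- pmin(pmax(b + step, -45), 15)
      if (max(abs(step)) < tol) break
    }
    beta[, g] <- b
  }
  beta
}

# Constrained fit for a pairwise contrast beta_A - beta_B = shift (natural
# log): a single free parameter over the pooled columns, with the shift
# absorbed into the A-column offsets.
.nb_fit_pooled <- function(y, offsets, is_A, phi, shift, maxit = 50,
                           tol = 1e-10) {
  o <- offsets + shift * as.numeric(is_A)
  .nb_fit_groups(y, o, groups = rep("all", ncol(y)), phi = phi,
                 maxit = maxit, tol = tol)[, 1]
}

.nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  size <- 1 / pmax(phi, DISPERSION_FLOOR)
  ll <- dnbinom(y, size = size, mu = mu, log = TRUE)
  rowSums(ll)
}

.mu_from_beta <- function(beta, offsets, groups) {
  groups <- as.factor(groups)
  exp(beta[, as.character(groups), drop = FALSE] +
        rep(offsets, each = nrow(beta)))
}

# ---- dispersion estimation ---------------------------------------------------

#' Estimate negative-binomial dispersions
#'
#' Common dispersion by maximizing the Cox-Reid adjusted profile likelihood
#' (APL) summed over genes on a dispersion grid; tagwise dispersions by
#' maximizing each gene's APL plus a common-likelihood prior weighted as
#' `prior_df / residual_df` (empirical-Bayes shrinkage toward the common
#' value, default 20 prior degrees of freedom). Group means are profiled
#' out by refitting at the common estimate.
#'
#' @param x a [count_matrix()].
#' @param design a [sample_design()] whose `group` column defines the
#'   one-way layout; every group needs at least one sample and the layout
#'   at least one residual degree of freedom.
#' @param norm_factors optional TMM factors; effective library sizes are
#'   `library_sizes * norm_factors`.
#' @param prior_df prior degrees of freedom for shrinkage (default 20).
#' @param grid_length number of grid points (default 41) spanning
#'   `grid_range`.
#' @param grid_range dispersion range searched (default `c(1e-6, 4)`,
#'   log-spaced).
#' @return List of class `"dispersion_estimates"`: `common` (scalar),
#'   `tagwise` (named per-gene vector, floored at 1e-8), `prior_df`.
#' @export
estimate_dispersions <- function(x, design, norm_factors = NULL,
                                 prior_df = 20, grid_length = 41,
                                 grid_range = c(1e-6, 4)) {
  y <- x$counts
  stopifnot(nrow(design) == ncol(y))
  groups <- factor(design$group)
  df_resid <- ncol(y) - nlevels(groups)
  if (df_resid < 1) stop("no residual degrees of freedom in the design")
  eff <- x$library_sizes * (if (is.null(norm_factors)) 1 else
    norm_factors[colnames(y)])
  offsets <- log(eff)
  grid <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                  length.out = grid_length))

  apl_matrix <- function(beta) {
    mu <- .mu_from_beta(beta, offsets, groups)
    out <- vapply(grid, function(phi) {
      ll <- .nb_loglik(y, mu, phi)
      # Cox-Reid: 0.5 log det(X'WX); diagonal for a one-way layout
      w <- mu / (1 + phi * mu)
      cr <- 0
      for (lev in levels(groups)) {
        S <- rowSums(w[, groups == lev, drop = FALSE])
        cr <- cr + 0.5 * log(pmax(S, 1e-300))
      }
      ll - cr
    }, numeric(nrow(y)))
    matrix(out, nrow = nrow(y), ncol = length(grid))
  }

  beta <- .nb_fit_groups(y, offsets, groups, phi = rep(0.1, nrow(y)))
  apl <- apl_matrix(beta)
  common <- .grid_argmax(colSums(apl), grid)
  # profile out the means at the common value and rescore
  beta <- .nb_fit_groups(y, offsets, groups, phi = rep(common, nrow(y)))
  apl <- apl_matrix(beta)
  common <- .grid_argmax(colSums(apl), grid)

  prior_weight <- prior_df / df_resid
  apl_bar <- colMeans(apl)
  tagwise <- vapply(seq_len(nrow(y)), function(g) {
    .grid_argmax(apl[g, ] + prior_weight * apl_bar, grid)
  }, numeric(1))
  tagwise <- pmax(tagwise, DISPERSION_FLOOR)
  names(tagwise) <- rownames(y)
  structure(list(common = max(common, DISPERSION_FLOOR), tagwise = tagwise,
                 prior_df = prior_df, df_residual = df_resid),
            class = "dispersion_estimates")
}

# Argmax on a log-spaced grid with local quadratic refinement.
.grid_argmax <- function(score, grid) {
  i <- which.max(score)
  if (i == 1 || i == length(grid)) return(grid[i])
  lx <- log(grid[(i - 1):(i + 1)])
  sy <- score[(i - 1):(i + 1)]
  denom <- (sy[1] - 2 * sy[2] + sy[3])
  if (!is.finite(denom) || denom >= 0) return(grid[i])
  xhat <- lx[2] - 0.5 * (lx[3] - lx[1]) / 2 * (sy[3] - sy[1]) / denom
  exp(min(max(xhat, lx[1]), lx[3]))
}

#' @export
print.dispersion_estimates <- function(x, ...) {
  cat("dispersion_estimates: common =", signif(x$common, 4),
      "| tagwise range =", paste(signif(range(x$tagwise), 4), collapse = " - "),
      "| prior_df =", x$prior_df, "\n")
  invisible(x)
}

# ---- contrast testing --------------------------------------------------------

.parse_contrast <- function(contrast, groups) {
  if (length(contrast) == 1 && grepl("-", contrast)) {
    parts <- trimws(strsplit(contrast, "-", fixed = TRUE)[[1]])
  } else {
    parts <- as.character(contrast)
  }
  if (length(parts) != 2) {
    stop("contrast must be a pairwise difference, e.g. \"STE_stamen - FER_stamen\"")
  }
  missing <- setdiff(parts, levels(groups))
  if (length(missing)) {
    stop("contrast group(s) not in design: ", paste(missing, collapse = ", "))
  }
  parts
}

#' Threshold differential-expression test for a pairwise contrast
#'
#' Fits a per-gene negative-binomial GLM (log link, effective-library-size
#' offsets, empirical-Bayes tagwise dispersions) to the two contrasted
#' groups and reports a likelihood-ratio test. With `lfc_threshold = 0`
#' this is the two-sided test of a zero contrast; with a positive
#' threshold it is a TREAT-style test that |log2 fold-change| exceeds the
#' threshold: the null is the composite |lfc| <= threshold, scored at both
#' boundaries via signed root deviances (tail probabilities summed, capped
#' at 1) and floored at the unthresholded p so the threshold test is never
#' more significant. FDR is Benjamini-Hochberg within the tested gene set.
#'
#' @param x a [count_matrix()].
#' @param design a [sample_design()] matching the columns of `x`.
#' @param dispersions a [estimate_dispersions()] result, or a numeric
#'   dispersion (scalar or per-gene) used as-is.
#' @param contrast `"A - B"` (group names from `design$group`) or
#'   `c("A", "B")`; positive log2 fold-changes mean higher expression in A.
#' @param lfc_threshold log2 fold-change threshold (default 1.25; use 0 for
#'   the plain test).
#' @param alpha FDR significance level (default 0.05).
#' @param norm_factors optional TMM factors.
#' @return A `data.frame` of class `"de_result"` with columns `gene_id`,
#'   `log2fc`, `p`, `fdr`, `significant`, `direction` and attribute
#'   `contrast`.
#' @export
test_contrast <- function(x, design, dispersions, contrast,
                          lfc_threshold = 1.25, alpha = 0.05,
                          norm_factors = NULL) {
  y <- x$counts
  stopifnot(nrow(design) == ncol(y))
  groups <- factor(design$group)
  parts <- .parse_contrast(contrast, groups)
  phi <- .dispersion_vector(dispersions, rownames(y))
  eff <- x$library_sizes * (if (is.null(norm_factors)) 1 else
    norm_factors[colnames(y)])

  J <- which(groups %in% parts)
  yAB <- y[, J, drop = FALSE]
  oAB <- log(eff[J])
  gAB <- droplevels(groups[J])
  is_A <- gAB == parts[1]
  if (sum(is_A) < 1 || sum(!is_A) < 1) stop("empty contrast group")

  beta <- .nb_fit_groups(yAB, oAB, gAB, phi)
  mu_full <- .mu_from_beta(beta, oAB, gAB)
  ll_full <- .nb_loglik(yAB, mu_full, phi)
  b <- beta[, parts[1]] - beta[, parts[2]]  # natural log
  log2fc <- b / log(2)

  ll_at <- function(shift) {
    b0 <- .nb_fit_pooled(yAB, oAB, is_A, phi, shift)
    mu <- exp(b0 %o% rep(1, ncol(yAB))) *
      rep(exp(oAB + shift * as.numeric(is_A)), each = nrow(yAB))
    .nb_loglik(yAB, mu, phi)
  }

  lr0 <- pmax(2 * (ll_full - ll_at(0)), 0)
  p0 <- pchisq(lr0, df = 1, lower.tail = FALSE)
  if (lfc_threshold > 0) {
    s <- lfc_threshold * log(2)
    sgn <- ifelse(b >= 0, 1, -1)
    ll_near <- ll_at_signed(yAB, oAB, is_A, phi, s, sgn)
    ll_far <- ll_at_signed(yAB, oAB, is_A, phi, -s, sgn)
    r_near <- sqrt(pmax(2 * (ll_full - ll_near$ll), 0))
    r_far <- sqrt(pmax(2 * (ll_full - ll_far$ll), 0))
    # signed root at the near boundary: negative when |b| falls short of it
    r_near <- ifelse(abs(b) >= s, r_near, -r_near)
    p <- pnorm(r_near, lower.tail = FALSE) + pnorm(r_far, lower.tail = FALSE)
    p <- pmin(pmax(p, p0), 1)
  } else {
    p <- p0
  }
  fdr <- bh_fdr(p)
  significant <- fdr <= alpha
  direction <- ifelse(!significant, "none", ifelse(log2fc > 0, "up", "down"))
  out <- data.frame(gene_id = rownames(y), log2fc = log2fc, p = p, fdr = fdr,
                    significant = significant, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- paste(parts[1], "-", parts[2])
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("de_result", "data.frame")
  out
}

# Constrained log-likelihood at a boundary on the side of the estimate:
# shift_mag is +s (near) or -s (far) relative to the sign of each gene's
# estimate. Genes are grouped by sign to keep the fits vectorized.
ll_at_signed <- function(y, o, is_A, phi, shift_mag, sgn) {
  ll <- numeric(nrow(y))
  for (sg in unique(sgn)) {
    idx <- which(sgn == sg)
    b0 <- .nb_fit_pooled(y[idx, , drop = FALSE], o, is_A, phi[idx],
                         sg * shift_mag)
    mu <- exp(b0 %o% rep(1, ncol(y))) *
      rep(exp(o + sg * shift_mag * as.numeric(is_A)), each = length(idx))
    ll[idx] <- .nb_loglik(y[idx, , drop = FALSE], mu, phi[idx])
  }
  list(ll = ll)
}

.dispersion_vector <- function(dispersions, gene_ids) {
  if (inherits(dispersions, "dispersion_estimates")) {
    phi <- dispersions$tagwise[gene_ids]
    if (anyNA(phi)) stop("dispersions missing for some genes")
    return(unname(phi))
  }
  phi <- as.numeric(dispersions)
  if (length(phi) == 1) phi <- rep(phi, length(gene_ids))
  if (length(phi) != length(gene_ids)) {
    stop("dispersion vector length must match the gene count")
  }
  pmax(phi, DISPERSION_FLOOR)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment; output order matches input order.
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted values (FDR) in the original order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# ---- MDS ---------------------------------------------------------------------

#' Leading log-fold-change multidimensional scaling
#'
#' Pairwise sample distance = root-mean-square of the `top_genes` largest
#' absolute log2 differences of log-CPM (prior count added on the CPM scale)
#' for that sample pair; the two-dimensional embedding comes from classical
#' metric scaling of that distance matrix.
#'
#' @param cpm_matrix genes x samples CPM matrix (see [cpm()]).
#' @param top_genes number of top divergent genes per pair (default 500,
#'   capped at the gene count).
#' @param prior_cpm prior added to CPM before taking logs (default 2).
#' @param dims embedding dimensions (default 2); needs at least `dims + 1`
#'   samples.
#' @return List with `coordinates` (samples x dims) and `distances`
#'   (symmetric matrix, zero diagonal).
#' @export
mds_leading_logfc <- function(cpm_matrix, top_genes = 500, prior_cpm = 2,
                              dims = 2) {
  ns <- ncol(cpm_matrix)
  if (ns < dims + 1) stop("need at least ", dims + 1, " samples")
  lcpm <- log2(cpm_matrix + prior_cpm)
  k <- min(top_genes, nrow(lcpm))
  D <- matrix(0, ns, ns, dimnames = list(colnames(cpm_matrix),
                                         colnames(cpm_matrix)))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      d2 <- (lcpm[, i] - lcpm[, j])^2
      top <- sort(d2, decreasing = TRUE)[seq_len(k)]
      D[i, j] <- D[j, i] <- sqrt(mean(top))
    }
  }
  coords <- cmdscale(D, k = dims)
  colnames(coords) <- paste0("dim", seq_len(dims))
  list(coordinates = coords, distances = D)
}
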