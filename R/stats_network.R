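#' Correlation statistics and the clinical-metabolite-strain network
#'
#' Spearman rank correlation with a Student-t p-value approximation (the
#' convention of the usual correlation-matrix tools, which reproduces the
#' printed clinical correlations of single-subject intervention studies at
#' n = 7) plus an exact permutation option for small n;
#' Benjamini-Hochberg FDR adjustment; and assembly of the tri-partite
#' network linking clinical parameters, metabolites and producing strains.
#'
#' @name stats_network
NULL

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average-ranked values (for tie-free
#' data this equals 1 - 6*sum(d^2)/(n(n^2-1))). The two-sided p-value uses
#' t = rho*sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom, or exact
#' enumeration of all n! rank permutations (`method = "exact"`, tie-free
#' data, n <= 9 only). |rho| = 1 is reported as p = 0 with the
#' `degenerate` flag set.
#'
#' @param x,y numeric series of equal length n >= 4.
#' @param method `"t"` (default) or `"exact"`.
#' @return list with `rho`, `p` (two-sided), `n`, `method`, `degenerate`.
#' @export
spearman <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("series length mismatch")
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input series")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  degenerate <- abs(rho) >= 1 - 1e-12
  if (method == "exact") {
    if (n > 9) stop("exact permutation p only supported for n <= 9")
    if (anyDuplicated(rx) || anyDuplicated(ry))
      stop("exact permutation p requires tie-free data")
    ds <- .spearman_null_d2(n)
    rhos <- 1 - 6 * ds / (n * (n^2 - 1))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (degenerate) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, method = method, degenerate = degenerate)
}

# all permutations of 1..n (rows), n <= 9
.perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- .perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p
    q[q >= i] <- q[q >= i] + 1L
    cbind(rep(i, nrow(q)), q)
  }))
}

# null distribution of sum(d^2) between 1..n and a uniform permutation
.spearman_null_cache <- new.env(parent = emptyenv())
.spearman_null_d2 <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_null_cache[[key]]))
    return(.spearman_null_cache[[key]])
  P <- .perms(n)
  ds <- rowSums(sweep(P, 2, seq_len(n))^2)
  .spearman_null_cache[[key]] <- ds
  ds
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply p_(i) by m/i,
#' enforce monotonicity from the largest down, cap at 1, restore the
#' original order.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
fdr_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}

#' Correlate metabolite series with clinical parameters
#'
#' Tests every metabolite x clinical pair over the shared timepoint axis,
#' FDR-adjusts across the full pair family, and flags edges passing both
#' thresholds (strict inequalities; |rho| is compared so strong negative
#' correlations qualify). Constant series are skipped with a warning.
#'
#' @param metabolite_table numeric matrix or data.frame, samples (rows,
#'   in timepoint order) x metabolites (columns).
#' @param clinical data.frame with a `timepoint` column and one numeric
#'   column per clinical parameter, same row order.
#' @param r_thresh correlation threshold (default 0.7).
#' @param p_thresh FDR-adjusted p threshold (default 0.1).
#' @param method p-value method passed to [spearman()].
#' @return data.frame of all tested pairs: `metabolite`, `clinical`,
#'   `rho`, `p_raw`, `p_fdr`, `sign`, `kept`.
#' @export
correlate_features <- function(metabolite_table, clinical, r_thresh = 0.7,
                               p_thresh = 0.1, method = "t") {
  mt <- as.matrix(metabolite_table)
  cl <- clinical[, setdiff(names(clinical), "timepoint"), drop = FALSE]
  if (nrow(mt) != nrow(cl))
    stop("metabolite table and clinical series disagree on timepoints")
  if (nrow(mt) < 4) stop("need at least 4 shared timepoints")
  const_m <- apply(mt, 2, function(v) stats::sd(v) == 0)
  const_c <- vapply(cl, function(v) stats::sd(v) == 0, FALSE)
  if (any(const_m))
    warning("skipped constant metabolite series: ",
            paste(colnames(mt)[const_m], collapse = ", "))
  if (any(const_c))
    warning("skipped constant clinical series: ",
            paste(names(cl)[const_c], collapse = ", "))
  mt <- mt[, !const_m, drop = FALSE]
  cl <- cl[, !const_c, drop = FALSE]
  pairs <- expand.grid(metabolite = colnames(mt), clinical = names(cl),
                       stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$metabolite, pairs$clinical), , drop = FALSE]
  rownames(pairs) <- NULL
  res <- lapply(seq_len(nrow(pairs)), function(i)
    spearman(mt[, pairs$metabolite[i]], cl[[pairs$clinical[i]]],
             method = method))
  pairs$rho <- vapply(res, `[[`, 0, "rho")
  pairs$p_raw <- vapply(res, `[[`, 0, "p")
  pairs$p_fdr <- fdr_bh(pairs$p_raw)
  pairs$sign <- ifelse(pairs$rho >= 0, "+", "-")
  pairs$kept <- abs(pairs$rho) > r_thresh & pairs$p_fdr < p_thresh
  pairs
}

#' Leptin/adiponectin ratio
#'
#' Appends the elementwise leptin / adiponectin ratio, a derived obesity
#' marker, as a clinical feature.
#'
#' @param clinical data.frame with `leptin` and `adiponectin` columns.
#' @return the clinical data.frame with a `lep_adip_ratio` column.
#' @export
derived_ratio <- function(clinical) {
  if (!all(c("leptin", "adiponectin") %in% names(clinical)))
    stop("clinical series must contain leptin and adiponectin")
  zero <- which(clinical$adiponectin == 0)
  if (length(zero) > 0)
    stop("adiponectin is zero at timepoint ",
         clinical$timepoint[zero[1]], "; ratio undefined")
  clinical$lep_adip_ratio <- clinical$leptin / clinical$adiponectin
  clinical
}

#' Build the clinical-metabolite-strain network
#'
#' Nodes are the focus clinical parameters, the metabolites with a kept
#' correlation edge to one of them, and the strains with a positive
#' production share for those metabolites. Edges are typed `correlation`
#' (attributes sign, rho, p_fdr) and `production` (attribute share).
#' Isolated nodes are dropped; node and edge order is deterministic.
#'
#' @param edges output of [correlate_features()].
#' @param contributions data.frame with `metabolite`, `strain`, `share`
#'   (one row per pair; duplicates are merged by summing shares, with a
#'   warning).
#' @param focus clinical parameters to include (default BMI, leptin,
#'   adiponectin).
#' @return an [igraph::graph] with vertex attribute `type` in
#'   \{clinical, metabolite, strain\}.
#' @export
build_network <- function(edges, contributions = NULL,
                          focus = c("BMI", "leptin", "adiponectin")) {
  kept <- edges[edges$kept & edges$clinical %in% focus, , drop = FALSE]
  kept <- kept[order(kept$metabolite, kept$clinical), , drop = FALSE]
  if (nrow(kept) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  mets <- sort(unique(kept$metabolite))
  clin <- sort(unique(kept$clinical))

  prod <- data.frame(metabolite = character(0), strain = character(0),
                     share = numeric(0))
  if (!is.null(contributions) && nrow(contributions) > 0) {
    prod <- contributions[contributions$share > 0 &
                            contributions$metabolite %in% mets,
                          c("metabolite", "strain", "share"), drop = FALSE]
    if (nrow(prod) > 0 && anyDuplicated(prod[, c("metabolite", "strain")])) {
      warning("duplicate (metabolite, strain) contribution records merged; ",
              "shares summed")
      prod <- stats::aggregate(share ~ metabolite + strain, data = prod,
                               FUN = sum)
    }
    prod <- prod[order(prod$metabolite, prod$strain), , drop = FALSE]
  }
  strains <- sort(unique(prod$strain))

  nodes <- data.frame(
    name = c(clin, mets, strains),
    type = c(rep("clinical", length(clin)), rep("metabolite", length(mets)),
             rep("strain", length(strains))),
    stringsAsFactors = FALSE)
  edge_df <- rbind(
    data.frame(from = kept$metabolite, to = kept$clinical,
               etype = "correlation", sign = kept$sign, rho = kept$rho,
               p_fdr = kept$p_fdr, share = NA_real_,
               stringsAsFactors = FALSE),
    if (nrow(prod) > 0)
      data.frame(from = prod$metabolite, to = prod$strain,
                 etype = "production", sign = NA_character_, rho = NA_real_,
                 p_fdr = NA_real_, share = prod$share,
                 stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(edge_df, directed = FALSE, vertices = nodes)
}

#' Write a network in GraphML format
#'
#' @param graph an [igraph::graph] from [build_network()].
#' @param path output file path.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
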