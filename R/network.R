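#' Weighted coexpression adjacency
#'
#' Soft-thresholded adjacency `a_ij = |cor(x_i, x_j)|^power` (unsigned
#' network; Pearson correlation over samples), with unit diagonal. In the
#' signed variant `a_ij = ((1 + cor) / 2)^power`.
#'
#' @param expr Genes x samples matrix, >= 3 samples, no zero-variance gene.
#' @param power Soft-threshold exponent (>= 1).
#' @param mode "unsigned" (default) or "signed".
#' @return Symmetric genes x genes adjacency matrix with values in `[0, 1]`.
#' @export
adjacency <- function(expr, power, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(expr))
  if (power < 1) stop("power must be >= 1")
  if (ncol(expr) < 3L) stop("adjacency needs >= 3 samples")
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(rownames(expr)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(expr))
  a <- if (mode == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Scale-free topology fit of an adjacency matrix
#'
#' Computes each gene's connectivity `k_i = sum_{j != i} a_ij`, bins the
#' connectivities into `n_bins` equal-width bins, and regresses
#' `log10(frequency)` on `log10(mean k)` over non-empty bins. The signed fit
#' index is `-sign(slope) * R^2`, so power-law-like (decreasing) degree
#' distributions score positively.
#'
#' @param adj Adjacency matrix over >= 20 genes.
#' @param n_bins Number of equal-width connectivity bins (default 10).
#' @return List with `r_squared` (signed), `slope`, `mean_k`, `median_k`.
#' @export
scale_free_fit <- function(adj, n_bins = 10L) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (nrow(adj) < 20L) stop("scale-free fit needs >= 20 genes")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  fit <- scale_free_fit_k(k, n_bins = n_bins)
  c(fit, list(mean_k = mean(k), median_k = stats::median(k)))
}

#' Scale-free fit from a connectivity vector
#'
#' The binning/regression core of [scale_free_fit()], usable directly on a
#' degree (connectivity) sequence.
#'
#' @param k Numeric vector of node connectivities.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `r_squared` (signed) and `slope`.
#' @export
scale_free_fit_k <- function(k, n_bins = 10L) {
  if (diff(range(k)) < 1e-12) stop("fewer than 3 non-empty connectivity bins")
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mean_k <- tapply(k, bin, mean)
  keep <- freq > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(keep) < 3L) stop("fewer than 3 non-empty connectivity bins")
  x <- log10(mean_k[keep])
  y <- log10(freq[keep] / sum(freq))
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  list(r_squared = -sign(slope) * r2, slope = slope)
}

#' Scan soft-threshold powers for scale-free fit
#'
#' Evaluates the signed scale-free fit index and connectivity summaries for
#' each candidate power. The correlation matrix is computed once and raised to
#' each power.
#'
#' @param expr Genes x samples matrix.
#' @param powers Candidate powers (default 1:20).
#' @param n_bins Bins for the fit (default 10).
#' @param mode Network mode, see [adjacency()].
#' @return data.frame (class `power_scan`) with columns power, r_squared,
#'   slope, mean_k, median_k.
#' @export
power_scan <- function(expr, powers = 1:20, n_bins = 10L,
                       mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  base <- adjacency(expr, power = 1, mode = mode)
  diag(base) <- 0
  rows <- lapply(powers, function(p) {
    k <- rowSums(base^p)
    fit <- tryCatch(scale_free_fit_k(k, n_bins = n_bins),
                    error = function(e) list(r_squared = NA_real_,
                                             slope = NA_real_))
    data.frame(power = p, r_squared = fit$r_squared, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("power_scan", "data.frame"))
}

#' Pick the soft-threshold power
#'
#' Returns the smallest power whose signed scale-free fit index reaches
#' `r2_threshold`; if no power crosses, returns the power with the maximal fit
#' index and warns.
#'
#' @param scan A [power_scan()] result.
#' @param r2_threshold Fit-index threshold (default 0.80).
#' @return Selected power (scalar).
#' @export
pick_power <- function(scan, r2_threshold = 0.80) {
  stopifnot(nrow(scan) > 0L)
  ok <- which(!is.na(scan$r_squared) & scan$r_squared >= r2_threshold)
  if (length(ok)) return(scan$power[ok[1L]])
  best <- which.max(scan$r_squared)
  warning("no power reaches the scale-free fit threshold ", r2_threshold,
          "; falling back to power ", scan$power[best],
          " (R^2 = ", signif(scan$r_squared[best], 3), ")")
  scan$power[best]
}

#' Topological overlap similarity
#'
#' For adjacency `a` with connectivity `k_i = sum_{u != i} a_iu` and shared
#' neighbourhood `l_ij = sum_{u != i,j} a_iu a_uj`:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` and `TOM_ii = 1`.
#' Denominators below 1e-10 yield 0.
#'
#' @param adj Symmetric adjacency matrix, unit diagonal, values in `[0, 1]`.
#' @return Symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                     # zero diagonal on a => sum over u != i, j
  num <- l + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- ifelse(den < 1e-10, 0, num / den)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Average-linkage hierarchical clustering
#'
#' UPGMA tree over a symmetric dissimilarity matrix (typically `1 - TOM`).
#'
#' @param diss Symmetric dissimilarity matrix with zero diagonal, no NaN.
#' @return An [stats::hclust] object.
#' @export
average_linkage <- function(diss) {
  stopifnot(is.matrix(diss), nrow(diss) == ncol(diss))
  if (anyNA(diss)) stop("dissimilarity contains NA/NaN")
  if (any(abs(diag(diss)) > 1e-12)) stop("dissimilarity diagonal must be zero")
  if (max(abs(diss - t(diss))) > 1e-8) stop("dissimilarity must be symmetric")
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Module colour palette
#'
#' Colour names assigned to module labels in the conventional order used by
#' coexpression analyses; label 0 is always "grey".
#' @param n Number of proper modules.
#' @return Character vector of n colour names.
#' @export
module_colors <- function(n) {
  pal <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
           "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
           "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
           "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
           "darkgrey", "orange", "darkorange", "white", "skyblue",
           "saddlebrown", "steelblue", "paleturquoise", "violet",
           "darkolivegreen", "darkmagenta")
  if (n <= length(pal)) pal[seq_len(n)] else
    c(pal, paste0("module", seq_len(n - length(pal))))[seq_len(n)]
}

#' Detect modules by cutting the dendrogram with a minimum size
#'
#' With `method = "adaptive"` (the default) the cut height is chosen by
#' scanning every distinct merge height: among the cuts yielding the maximal
#' number of clusters of at least `min_module_size` genes, the one whose
#' clusters were assembled lowest in the tree (minimal mean cluster node
#' height) wins — coherent modules complete low in the dendrogram while
#' noise agglomerations only assemble near the root. With
#' `method = "static"` the tree is cut at `cut_quantile` times the maximum
#' merge height. In both cases clusters of at least `min_module_size` genes
#' become modules, labelled 1..M by decreasing size (ties broken by first
#' gene order); all remaining genes get label 0 ("grey"). A module-membership
#' refinement pass is available separately via [refine_modules()].
#'
#' @param dend An [stats::hclust] tree over the genes.
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_quantile Fraction of the maximum merge height at which to cut
#'   when `method = "static"` (default 0.99).
#' @param method "adaptive" (merge-height scan) or "static" (quantile cut).
#' @return Object of class `module_assignment`: list with `labels` (named
#'   integer vector, 0 = unassigned), `colors` (per-gene colour names),
#'   `sizes` (named integer vector per module label), `cut_height`.
#' @export
detect_modules <- function(dend, min_module_size = 30L, cut_quantile = 0.99,
                           method = c("adaptive", "static")) {
  method <- match.arg(method)
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$order)
  if (n < min_module_size) stop("fewer genes than min_module_size")
  if (method == "static") {
    cut_height <- cut_quantile * max(dend$height)
  } else {
    hs <- sort(unique(dend$height))
    cls <- stats::cutree(dend, h = hs)
    if (is.null(dim(cls))) cls <- matrix(cls, ncol = 1L,
                                         dimnames = list(names(cls), NULL))
    counts <- apply(cls, 2L, function(cl) sum(table(cl) >= min_module_size))
    cand <- which(counts == max(counts))
    # representative leaf of every internal node, for locating each merge
    nm <- nrow(dend$merge)
    rep_leaf <- integer(nm)
    for (j in seq_len(nm)) {
      a <- dend$merge[j, 1L]
      rep_leaf[j] <- if (a < 0) -a else rep_leaf[a]
    }
    mean_node_height <- vapply(cand, function(i) {
      cl <- cls[, i]
      sz <- table(cl)
      big <- as.integer(names(sz)[sz >= min_module_size])
      inside <- dend$height <= hs[i]
      mean(vapply(big, function(b) {
        within <- inside & cl[rep_leaf] == b
        if (any(within)) max(dend$height[within]) else 0
      }, numeric(1L)))
    }, numeric(1L))
    cut_height <- hs[cand[which.min(mean_node_height)]]
  }
  cl <- stats::cutree(dend, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  # order retained clusters by decreasing size, ties by first occurrence
  first_idx <- vapply(big, function(g) which(cl == as.integer(g))[1L], integer(1L))
  ord <- big[order(-as.integer(sizes[big]), first_idx)]
  labels <- integer(n)
  names(labels) <- names(cl)
  for (i in seq_along(ord)) labels[cl == as.integer(ord[i])] <- i
  colors <- c("grey", module_colors(length(ord)))[labels + 1L]
  names(colors) <- names(labels)
  msizes <- table(labels[labels > 0])
  structure(list(labels = labels, colors = colors,
                 sizes = stats::setNames(as.integer(msizes), names(msizes)),
                 cut_height = cut_height),
            class = "module_assignment")
}

#' Refine a module assignment by module membership
#'
#' Reassignment passes in the spirit of the partitioning step used after
#' tree cutting in coexpression analyses, iterated until the labels
#' stabilize (at most `max_iter` rounds): each assigned gene moves to the
#' module whose eigengene it correlates with most strongly (in absolute
#' value), and an unassigned gene is rescued into a module when its best
#' absolute module membership exceeds `kme_rescue`. Modules that fall below
#' `min_module_size` afterwards, or whose eigengene explains less than
#' `min_var_explained` of the module variance (pure-noise clusters of 30
#' genes sit near the random-matrix noise floor of roughly 0.15 at these
#' sample sizes, coherent modules far above it), are dissolved into grey.
#' Labels are renumbered by decreasing size.
#'
#' @param expr Genes x samples matrix matching the assignment.
#' @param assignment A [detect_modules()] result.
#' @param min_module_size Minimum module size kept after refinement.
#' @param kme_rescue Absolute kME above which a grey gene joins its best
#'   module (default 0.5).
#' @param min_var_explained Minimum share of module variance the eigengene
#'   must explain for the module to survive (default 0.25).
#' @param max_iter Maximum reassignment rounds (default 10).
#' @return A refined `module_assignment`.
#' @export
refine_modules <- function(expr, assignment, min_module_size = 30L,
                           kme_rescue = 0.5, min_var_explained = 0.25,
                           max_iter = 10L) {
  stopifnot(inherits(assignment, "module_assignment"))
  labels <- assignment$labels[rownames(expr)]
  if (anyNA(labels)) stop("assignment does not cover all genes in expr")
  if (!any(labels > 0)) return(assignment)
  new <- labels
  for (iter in seq_len(max_iter)) {
    eg <- module_eigengenes(expr, new)
    kme <- abs(stats::cor(t(expr), eg$eigengenes))
    best <- eg$modules[max.col(kme, ties.method = "first")]
    best_k <- kme[cbind(seq_len(nrow(kme)),
                        max.col(kme, ties.method = "first"))]
    prev <- new
    upd <- prev
    upd[prev > 0] <- best[prev > 0]
    rescue <- prev == 0 & best_k > kme_rescue
    upd[rescue] <- best[rescue]
    # a module shrunk below the size floor dissolves; survivors keep labels
    szi <- table(upd[upd > 0])
    upd[upd %in% as.integer(names(szi)[szi < min_module_size])] <- 0L
    new <- upd
    if (!any(new > 0) || identical(new, prev)) break
  }
  if (!any(new > 0)) {
    return(structure(list(labels = new,
                          colors = stats::setNames(rep("grey", length(new)),
                                                   names(new)),
                          sizes = integer(0),
                          cut_height = assignment$cut_height),
                     class = "module_assignment"))
  }
  # dissolve undersized and incoherent modules, renumber by decreasing size
  sz <- table(new[new > 0])
  keep <- as.integer(names(sz)[sz >= min_module_size])
  keep <- keep[vapply(keep, function(m) {
    module_eigengene(expr, names(new)[new == m])$var_explained >=
      min_var_explained
  }, logical(1L))]
  new[!(new %in% keep)] <- 0L
  first_idx <- vapply(keep, function(m) which(new == m)[1L], integer(1L))
  ord <- keep[order(-as.integer(sz[as.character(keep)]), first_idx)]
  out <- integer(length(new))
  names(out) <- names(new)
  for (i in seq_along(ord)) out[new == ord[i]] <- i
  colors <- c("grey", module_colors(length(ord)))[out + 1L]
  names(colors) <- names(out)
  msizes <- table(out[out > 0])
  structure(list(labels = out, colors = colors,
                 sizes = stats::setNames(as.integer(msizes), names(msizes)),
                 cut_height = assignment$cut_height),
            class = "module_assignment")
}
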