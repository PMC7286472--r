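#' Ordinal stage trait
#'
#' Encodes ordered stage labels as scores 1..k in progression order and
#' z-scores them. The sign of every downstream trait correlation depends on
#' this coding (low score = earliest stage).
#'
#' @param stages Factor (ordered levels = progression order) or integer
#'   scores.
#' @return List of class `trait` with `score` (numeric) and `z` (z-scored).
#' @export
stage_trait <- function(stages) {
  score <- if (is.factor(stages)) as.integer(stages) else as.numeric(stages)
  if (length(unique(score)) < 2L) stop("trait needs >= 2 distinct stages")
  structure(list(score = score, z = as.numeric(scale(score))), class = "trait")
}

#' Pearson correlation with Student-t p-value
#'
#' Two-sided p from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `r` and `p`.
#' @export
cor_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# Vectorized gene-trait correlation with t-based p-values; rows of mat vs y.
row_cor_with_p <- function(mat, y) {
  n <- ncol(mat)
  r <- as.numeric(stats::cor(t(mat), y))
  r2 <- pmin(r^2, 1 - 1e-15)
  tval <- r * sqrt(n - 2) / sqrt(1 - r2)
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  list(r = r, p = pmin(p, 1))
}

#' Module eigengene
#'
#' First principal component of the gene-standardized module submatrix: the
#' per-sample scores of the leading right singular vector, rescaled to unit
#' variance and sign-aligned so it correlates positively with the module's
#' mean standardized profile.
#'
#' @param expr Genes x samples matrix.
#' @param genes Character or integer index of module members (>= 2 genes,
#'   none with zero variance).
#' @return List with `eigengene` (length = samples, unit variance) and
#'   `var_explained` (share of module variance carried by the first
#'   component).
#' @export
module_eigengene <- function(expr, genes) {
  sub <- expr[genes, , drop = FALSE]
  if (nrow(sub) < 2L) stop("module needs >= 2 genes")
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s) in module: ",
         paste(rownames(sub)[sds == 0], collapse = ", "))
  }
  zs <- t(scale(t(sub)))                    # standardize each gene
  sv <- svd(zs)
  pc <- sv$v[, 1L]
  me <- as.numeric(scale(pc))
  m <- colMeans(zs)
  align <- if (stats::sd(m) > 0) stats::cor(me, m) else NA_real_
  if (!is.na(align) && align < 0) me <- -me
  list(eigengene = me, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

#' Eigengenes for every module
#'
#' @param expr Genes x samples matrix.
#' @param labels Named integer module labels (0 = grey/unassigned, skipped).
#' @return List of class `module_eigengenes` with `eigengenes` (samples x
#'   modules matrix, columns "ME1", "ME2", ...) and `var_explained`.
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no proper modules")
  me <- matrix(NA_real_, nrow = ncol(expr), ncol = length(mods),
               dimnames = list(colnames(expr), paste0("ME", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    eg <- module_eigengene(expr, names(labels)[labels == mods[i]])
    me[, i] <- eg$eigengene
    ve[i] <- eg$var_explained
  }
  structure(list(eigengenes = me, var_explained = ve, modules = mods),
            class = "module_eigengenes")
}

#' Module significance and eigengene-trait correlation
#'
#' Module significance (MS) is the mean absolute gene-trait correlation over
#' module members; the eigengene-trait correlation and p-value come from the
#' module's first principal component. The grey module (label 0) is reported
#' but never eligible for selection.
#'
#' @param expr Genes x samples matrix.
#' @param trait A [stage_trait()] (or numeric vector).
#' @param labels Named integer module labels.
#' @param eigengenes Optional [module_eigengenes()] result (computed if NULL).
#' @return data.frame (class `module_trait_stats`): module, size, MS,
#'   me_trait_r, me_trait_p (NA for grey).
#' @export
module_significance <- function(expr, trait, labels, eigengenes = NULL) {
  y <- if (inherits(trait, "trait")) trait$z else as.numeric(trait)
  gs <- abs(row_cor_with_p(expr, y)$r)
  names(gs) <- rownames(expr)
  mods <- sort(unique(labels))
  if (is.null(eigengenes) && any(mods > 0)) {
    eigengenes <- module_eigengenes(expr, labels)
  }
  rows <- lapply(mods, function(m) {
    members <- names(labels)[labels == m]
    if (!length(members)) {
      warning("module ", m, " is empty; skipped")
      return(NULL)
    }
    ms <- mean(gs[members])
    if (m > 0) {
      cp <- cor_with_p(eigengenes$eigengenes[, paste0("ME", m)], y)
      data.frame(module = m, size = length(members), MS = ms,
                 me_trait_r = cp$r, me_trait_p = cp$p)
    } else {
      data.frame(module = 0L, size = length(members), MS = ms,
                 me_trait_r = NA_real_, me_trait_p = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("module_trait_stats", "data.frame"))
}

#' Select the trait-associated module
#'
#' Primary criterion: maximal MS over proper (non-grey) modules. The choice is
#' cross-checked against the module with maximal absolute eigengene-trait
#' correlation; a disagreement between the two criteria triggers a warning and
#' the MS winner is returned. Ties go to the lower label (the larger module).
#'
#' @param stats A [module_significance()] table.
#' @return Selected module label (integer), with attribute `agree` (logical).
#' @export
select_significant_module <- function(stats) {
  cand <- stats[stats$module > 0, , drop = FALSE]
  if (!nrow(cand)) stop("no proper module to select from")
  ms_win <- cand$module[order(-cand$MS, cand$module)][1L]
  me_win <- cand$module[order(-abs(cand$me_trait_r), cand$module)][1L]
  if (sum(cand$MS == max(cand$MS)) > 1L) {
    warning("MS tie; selecting the lower label (larger module)")
  }
  agree <- identical(ms_win, me_win)
  if (!agree) {
    warning("MS criterion selects module ", ms_win,
            " but eigengene-trait correlation selects module ", me_win,
            "; returning the MS winner")
  }
  structure(ms_win, agree = agree)
}

#' Per-gene screening statistics
#'
#' For each gene: `cor.Standard` / `p.Standard`, the plain Pearson gene-trait
#' correlation and its t-based p; `cor.Weighted` / `p.Weighted`, the trait
#' correlation of a network-weighted profile blending the standardized gene
#' with its module eigengene (`(1 - mix_weight) * z(x_i) + mix_weight * ME`);
#' and `kME`, the gene's correlation with each module eigengene. Grey genes
#' get no eigengene blending (`cor.Weighted = cor.Standard`).
#'
#' @param expr Genes x samples matrix.
#' @param trait A [stage_trait()] or numeric vector.
#' @param eigengenes A [module_eigengenes()] result.
#' @param labels Named integer module labels.
#' @param mix_weight Eigengene share of the blended profile in `[0, 1]`
#'   (default 0.5; 0 reproduces the plain correlation).
#' @return List of class `screening_stats`: `table` (data.frame gene, module,
#'   cor.Standard, p.Standard, cor.Weighted, p.Weighted) and `kME`
#'   (genes x modules matrix).
#' @export
screening_stats <- function(expr, trait, eigengenes, labels, mix_weight = 0.5) {
  if (mix_weight < 0 || mix_weight > 1) stop("mix_weight must be in [0, 1]")
  y <- if (inherits(trait, "trait")) trait$z else as.numeric(trait)
  std <- row_cor_with_p(expr, y)
  zs <- t(scale(t(expr)))
  me <- eigengenes$eigengenes
  kme <- stats::cor(t(expr), me)
  rownames(kme) <- rownames(expr)
  blended <- zs
  for (m in eigengenes$modules) {
    idx <- which(labels[rownames(expr)] == m)
    if (!length(idx)) next
    blended[idx, ] <- (1 - mix_weight) * zs[idx, , drop = FALSE] +
      mix_weight * matrix(me[, paste0("ME", m)], nrow = length(idx),
                          ncol = ncol(expr), byrow = TRUE)
  }
  wtd <- row_cor_with_p(blended, y)
  tab <- data.frame(gene = rownames(expr),
                    module = as.integer(labels[rownames(expr)]),
                    cor.Standard = std$r, p.Standard = std$p,
                    cor.Weighted = wtd$r, p.Weighted = wtd$p,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, kME = kme, mix_weight = mix_weight),
            class = "screening_stats")
}

#' Hub gene selection by the dual correlation rule
#'
#' Hubs are the genes of the selected module with both
#' `|cor.Standard| > threshold` and `|cor.Weighted| > threshold` (strict
#' inequalities), sorted by decreasing `|cor.Weighted|`.
#'
#' @param stats A [screening_stats()] result (or its `table`).
#' @param module Module label to screen.
#' @param threshold Correlation threshold (default 0.8).
#' @return data.frame of hub rows (possibly empty).
#' @export
identify_hubs <- function(stats, module, threshold = 0.8) {
  tab <- if (inherits(stats, "screening_stats")) stats$table else stats
  sel <- tab$module == module &
    abs(tab$cor.Standard) > threshold &
    abs(tab$cor.Weighted) > threshold
  out <- tab[sel, , drop = FALSE]
  out <- out[order(-abs(out$cor.Weighted)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene one-way ANOVA across stages
#'
#' Fixed-effects one-way ANOVA of each gene's expression across the stage
#' groups: `F` on `(k - 1, N - k)` df with its upper-tail p, floored at
#' 2.2e-16. Groups with within-group variance 0 and distinct means yield
#' `F = Inf`, reported at the p floor.
#'
#' @param expr Genes x samples matrix.
#' @param stages Factor of stage labels; every stage needs >= 2 samples.
#' @return data.frame gene, F, p.
#' @export
stage_anova <- function(expr, stages) {
  stages <- droplevels(as.factor(stages))
  k <- nlevels(stages)
  if (k < 2L) stop("ANOVA needs >= 2 stages")
  cnt <- table(stages)
  if (any(cnt < 2L)) {
    stop("stage(s) with < 2 samples: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  }
  N <- ncol(expr)
  g <- as.integer(stages)
  group_means <- t(apply(expr, 1L, function(x) tapply(x, g, mean)))
  grand <- rowMeans(expr)
  ss_between <- as.numeric((group_means - grand)^2 %*% as.numeric(cnt))
  fitted <- group_means[, g, drop = FALSE]
  ss_within <- rowSums((expr - fitted)^2)
  df1 <- k - 1L
  df2 <- N - k
  Fv <- (ss_between / df1) / (ss_within / df2)
  Fv[ss_within == 0 & ss_between > 0] <- Inf
  Fv[ss_within == 0 & ss_between == 0] <- 0
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  p[is.infinite(Fv)] <- 0
  p <- pmax(p, 2.2e-16)
  p[Fv == 0] <- 1
  data.frame(gene = rownames(expr), F = Fv, p = p, stringsAsFactors = FALSE)
}
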