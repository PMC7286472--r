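#' Simulation configuration for planted-module expression data
#'
#' Describes a synthetic microarray-style study with samples in four ordered
#' disease stages and genes organized in latent-factor coexpression modules.
#' Gene `i` of module `m` is generated as
#' `x_i = sqrt(rho_m) * f_m + sqrt(1 - rho_m) * noise_sd * eps_i`, where the
#' module factor is `f_m = beta_m * z + sqrt(1 - beta_m^2) * eta_m`, `z` is the
#' z-scored ordinal stage score and `eta_m`, `eps_i` are iid standard normal.
#' Background genes are pure noise. Optionally the first `n_hubs[m]` genes of a
#' module are planted hubs built as `a*z + b*eta_m + c*eps_i` with
#' `a = sign(beta_m) * hub_trait_cor`, so their population gene-trait
#' correlation is exactly `a` while they remain module members.
#'
#' @param n_samples_per_stage Integer vector of length 4, samples per ordered
#'   stage. Default `c(7, 6, 6, 3)`, the sizes of the four sequential stages
#'   (normal duct, adenoma, carcinoma in situ, invasive) in the training design
#'   this generator emulates.
#' @param module_sizes Integer vector, genes per planted module (each >= 1).
#' @param within_module_cor Numeric vector, factor loading squared `rho_m` per
#'   module, each in `[0, 1)`. At `noise_sd = 1` this is the expected pairwise
#'   within-module correlation.
#' @param trait_effect Numeric vector, `beta_m` per module in `[-1, 1]`:
#'   correlation of the module factor with the z-scored stage score.
#' @param n_background_genes Number of unassigned pure-noise genes.
#' @param noise_sd Standard deviation multiplier of the gene-specific noise.
#' @param n_hubs Integer vector, planted hub genes per module (0 = none).
#' @param hub_trait_cor Magnitude of the planted hub gene-trait correlation.
#' @param hub_noise_var Variance share of hub-specific noise (keeps multiple
#'   hubs from being collinear); must satisfy `hub_trait_cor^2 + hub_noise_var <= 1`.
#' @param baseline Additive constant so values resemble log2 intensities.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples_per_stage = c(7L, 6L, 6L, 3L),
                       module_sizes = c(60L, 50L, 40L),
                       within_module_cor = c(0.7, 0.7, 0.7),
                       trait_effect = c(-0.75, 0, 0),
                       n_background_genes = 150L,
                       noise_sd = 1,
                       n_hubs = rep(0L, length(module_sizes)),
                       hub_trait_cor = 0.85,
                       hub_noise_var = 0.1,
                       baseline = 8,
                       seed = 1L) {
  cfg <- list(n_samples_per_stage = as.integer(n_samples_per_stage),
              module_sizes = as.integer(module_sizes),
              within_module_cor = as.numeric(within_module_cor),
              trait_effect = as.numeric(trait_effect),
              n_background_genes = as.integer(n_background_genes),
              noise_sd = as.numeric(noise_sd),
              n_hubs = as.integer(n_hubs),
              hub_trait_cor = as.numeric(hub_trait_cor),
              hub_noise_var = as.numeric(hub_noise_var),
              baseline = as.numeric(baseline),
              seed = as.integer(seed))
  if (length(cfg$n_samples_per_stage) != 4L || any(cfg$n_samples_per_stage < 1L)) {
    stop("n_samples_per_stage must be 4 positive integers")
  }
  nm <- length(cfg$module_sizes)
  if (nm > 0L && any(cfg$module_sizes < 1L)) stop("module_sizes must all be >= 1")
  if (length(cfg$within_module_cor) != nm || length(cfg$trait_effect) != nm ||
      length(cfg$n_hubs) != nm) {
    stop("within_module_cor, trait_effect and n_hubs must match module_sizes in length")
  }
  if (any(cfg$within_module_cor < 0 | cfg$within_module_cor >= 1)) {
    stop("within_module_cor must lie in [0, 1)")
  }
  if (any(abs(cfg$trait_effect) > 1)) stop("trait_effect magnitudes must be <= 1")
  if (cfg$n_background_genes < 0L) stop("n_background_genes must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (any(cfg$n_hubs > cfg$module_sizes)) stop("n_hubs cannot exceed module size")
  if (cfg$hub_trait_cor < 0 || cfg$hub_trait_cor > 1) stop("hub_trait_cor must be in [0, 1]")
  if (cfg$hub_trait_cor^2 + cfg$hub_noise_var > 1) {
    stop("hub_trait_cor^2 + hub_noise_var must be <= 1")
  }
  total <- sum(cfg$module_sizes) + cfg$n_background_genes
  if (nm > 0L && any(cfg$module_sizes > total)) {
    stop("a module cannot exceed the total gene budget")
  }
  if (total < 1L) stop("no genes requested")
  class(cfg) <- "sim_config"
  cfg
}

#' Default ordered stage labels
#' @keywords internal
stage_levels <- function() c("normal", "adenoma", "carcinoma", "invasive")

#' Simulate a stage-structured expression matrix with planted modules
#'
#' @param config A [sim_config()].
#' @return List with elements:
#'   \describe{
#'     \item{expr}{genes x samples numeric matrix (log2-intensity-like).}
#'     \item{stages}{factor of ordered stage labels per sample.}
#'     \item{truth}{list: `module` (named integer vector, 0 = background),
#'       `hubs` (character vector of planted hub gene ids), `trait_effect`
#'       (per-module population factor-trait correlation), `factors`
#'       (samples x modules matrix of realized factors), `stage_z`
#'       (z-scored stage score).}
#'   }
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_samples_per_stage
  n <- sum(ns)
  stages <- factor(rep(stage_levels(), times = ns), levels = stage_levels())
  score <- as.integer(stages)
  z <- as.numeric(scale(score))

  nm <- length(config$module_sizes)
  total <- sum(config$module_sizes) + config$n_background_genes
  gene_ids <- sprintf("G%04d", seq_len(total))
  expr <- matrix(NA_real_, nrow = total, ncol = n,
                 dimnames = list(gene_ids, sprintf("S%02d", seq_len(n))))
  module <- integer(total)
  names(module) <- gene_ids
  hubs <- character(0)
  factors <- matrix(NA_real_, nrow = n, ncol = nm)
  if (nm > 0L) colnames(factors) <- paste0("M", seq_len(nm))

  row <- 0L
  for (m in seq_len(nm)) {
    beta <- config$trait_effect[m]
    rho <- config$within_module_cor[m]
    eta <- stats::rnorm(n)
    f <- beta * z + sqrt(1 - beta^2) * eta
    factors[, m] <- f
    nh <- config$n_hubs[m]
    for (g in seq_len(config$module_sizes[m])) {
      row <- row + 1L
      module[row] <- m
      if (g <= nh) {
        # hub gene-trait correlation holds exactly in-sample: the residual
        # (module factor + private noise) is orthogonalized against z
        a <- if (beta < 0) -config$hub_trait_cor else config$hub_trait_cor
        b <- sqrt(max(0, 1 - a^2 - config$hub_noise_var))
        raw <- b * eta + sqrt(config$hub_noise_var) * stats::rnorm(n)
        w <- stats::residuals(stats::lm(raw ~ z))
        w <- as.numeric(scale(w))
        expr[row, ] <- a * z + sqrt(1 - a^2) * w
        hubs <- c(hubs, gene_ids[row])
      } else {
        expr[row, ] <- sqrt(rho) * f +
          sqrt(1 - rho) * config$noise_sd * stats::rnorm(n)
      }
    }
  }
  if (config$n_background_genes > 0L) {
    bg <- matrix(config$noise_sd * stats::rnorm(config$n_background_genes * n),
                 nrow = config$n_background_genes)
    expr[row + seq_len(config$n_background_genes), ] <- bg
  }
  expr <- expr + config$baseline
  list(expr = expr,
       stages = stages,
       truth = list(module = module, hubs = hubs,
                    trait_effect = config$trait_effect,
                    factors = factors, stage_z = z))
}

#' Biotype whitelist for lncRNA transcripts
#'
#' The ten GENCODE gene types treated as lncRNA when reannotating probes.
#' @return Character vector of biotypes.
#' @export
lncrna_biotypes <- function() {
  c("lincRNA", "bidirectional_promoter_lncRNA", "macro_lncRNA", "antisense",
    "processed_transcript", "TEC", "3prime_overlapping_ncRNA",
    "sense_intronic", "non_coding", "sense_overlapping")
}

#' Configuration for the synthetic probe/transcript universe
#'
#' Emulates a 25-mer short-probe microarray platform: probe sets of
#' `probes_per_set` probes against a transcriptome annotated with lncRNA and
#' protein-coding biotypes. "Clean" sets target one lncRNA transcript with
#' exact unique probes; decoy classes are 1-mismatch sets, multi-mapping sets
#' (probes planted in transcripts of two genes), sparse sets (only 3 exact
#' probes), and clean-quality sets on protein-coding transcripts.
#'
#' @param n_clean_lncrna Number of clean lncRNA-targeting probe sets/genes.
#' @param n_protein_coding Number of clean-quality protein-coding decoy sets.
#' @param n_mismatch Number of 1-mismatch decoy sets.
#' @param n_multimap Number of multi-mapping decoy sets.
#' @param n_sparse Number of sparse (3 matching probes) decoy sets.
#' @param probes_per_set Probes per probe set (platform convention: 11).
#' @param probe_length Probe length in nucleotides (platform convention: 25).
#' @param transcript_length_range Min/max transcript length.
#' @param seed Integer seed.
#' @return Object of class `probe_universe_config`.
#' @export
probe_universe_config <- function(n_clean_lncrna = 30L,
                                  n_protein_coding = 5L,
                                  n_mismatch = 5L,
                                  n_multimap = 5L,
                                  n_sparse = 5L,
                                  probes_per_set = 11L,
                                  probe_length = 25L,
                                  transcript_length_range = c(300L, 900L),
                                  seed = 1L) {
  cfg <- list(n_clean_lncrna = as.integer(n_clean_lncrna),
              n_protein_coding = as.integer(n_protein_coding),
              n_mismatch = as.integer(n_mismatch),
              n_multimap = as.integer(n_multimap),
              n_sparse = as.integer(n_sparse),
              probes_per_set = as.integer(probes_per_set),
              probe_length = as.integer(probe_length),
              transcript_length_range = as.integer(transcript_length_range),
              seed = as.integer(seed))
  if (cfg$probe_length < 8L) stop("probe_length must be >= 8")
  if (cfg$probes_per_set < 4L) stop("probes_per_set must be >= 4")
  if (cfg$n_sparse > 0L && cfg$probes_per_set < 4L) stop("sparse sets need >= 4 probes")
  if (any(cfg$transcript_length_range < cfg$probe_length)) {
    stop("transcript lengths must be >= probe_length")
  }
  if (cfg$transcript_length_range[1L] > cfg$transcript_length_range[2L]) {
    stop("transcript_length_range must be increasing")
  }
  class(cfg) <- "probe_universe_config"
  cfg
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a probe/transcript universe with planted decoys
#'
#' @param config A [probe_universe_config()].
#' @return List with elements:
#'   \describe{
#'     \item{transcripts}{named [Biostrings::DNAStringSet].}
#'     \item{attrs}{data.frame transcript_id, gene_id, gene_symbol, biotype.}
#'     \item{probes}{data.frame probe_id, probeset_id, sequence.}
#'     \item{truth}{list: `clean_genes` (gene ids reannotation must retain),
#'       `probe_map` (data.frame probe_id, probeset_id, gene_id,
#'       transcript_id, class with classes clean / protein_coding / mismatch /
#'       multimap / sparse_match / sparse_nonmatch).}
#'   }
#' @export
simulate_probe_universe <- function(config = probe_universe_config()) {
  stopifnot(inherits(config, "probe_universe_config"))
  set.seed(config$seed)
  pl <- config$probe_length
  lr <- config$transcript_length_range
  wl <- lncrna_biotypes()

  classes <- c(rep("clean", config$n_clean_lncrna),
               rep("protein_coding", config$n_protein_coding),
               rep("mismatch", config$n_mismatch),
               rep("multimap", config$n_multimap),
               rep("sparse", config$n_sparse))
  n_sets <- length(classes)
  if (n_sets == 0L) stop("universe has no probe sets")

  tx_seqs <- character(0)
  attrs <- list()
  probes <- list()
  truth_map <- list()
  pid <- 0L

  new_transcript <- function(gene_id, symbol, biotype, seq = NULL) {
    if (is.null(seq)) seq <- random_dna(sample(lr[1L]:lr[2L], 1L))
    tid <- sprintf("TX%04d", length(tx_seqs) + 1L)
    tx_seqs[[tid]] <<- seq
    attrs[[length(attrs) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = gene_id, gene_symbol = symbol,
      biotype = biotype, stringsAsFactors = FALSE)
    tid
  }
  pick_probes <- function(seq, k) {
    # distinct windows; offsets 0-based
    offs <- sample.int(nchar(seq) - pl + 1L, min(k * 3L, nchar(seq) - pl + 1L)) - 1L
    subs <- substring(seq, offs + 1L, offs + pl)
    keep <- !duplicated(subs)
    offs <- offs[keep][seq_len(k)]
    subs <- subs[keep][seq_len(k)]
    if (anyNA(offs)) stop("transcript too short to host ", k, " distinct probes")
    list(offset = offs, seq = subs)
  }
  mutate_one <- function(seq) {
    pos <- ceiling(nchar(seq) / 2)
    old <- substring(seq, pos, pos)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    paste0(substring(seq, 1L, pos - 1L), new, substring(seq, pos + 1L))
  }

  for (s in seq_len(n_sets)) {
    cls <- classes[s]
    setid <- sprintf("PS%03d_at", s)
    gene_id <- sprintf("GENE%04d", s)
    symbol <- sprintf("%s-%03d", toupper(substr(cls, 1L, 3L)), s)
    biotype <- if (cls == "protein_coding") "protein_coding" else sample(wl, 1L)
    tid <- new_transcript(gene_id, symbol, biotype)
    seq <- tx_seqs[[tid]]
    k <- config$probes_per_set
    if (cls %in% c("clean", "protein_coding")) {
      pk <- pick_probes(seq, k)
      for (j in seq_len(k)) {
        pid <- pid + 1L
        probes[[pid]] <- data.frame(probe_id = sprintf("P%05d", pid),
                                    probeset_id = setid, sequence = pk$seq[j],
                                    stringsAsFactors = FALSE)
        truth_map[[pid]] <- data.frame(probe_id = sprintf("P%05d", pid),
                                       probeset_id = setid, gene_id = gene_id,
                                       transcript_id = tid, class = cls,
                                       stringsAsFactors = FALSE)
      }
    } else if (cls == "mismatch") {
      pk <- pick_probes(seq, k)
      for (j in seq_len(k)) {
        pid <- pid + 1L
        probes[[pid]] <- data.frame(probe_id = sprintf("P%05d", pid),
                                    probeset_id = setid,
                                    sequence = mutate_one(pk$seq[j]),
                                    stringsAsFactors = FALSE)
        truth_map[[pid]] <- data.frame(probe_id = sprintf("P%05d", pid),
                                       probeset_id = setid, gene_id = gene_id,
                                       transcript_id = tid, class = cls,
                                       stringsAsFactors = FALSE)
      }
    } else if (cls == "multimap") {
      pk <- pick_probes(seq, k)
      # second gene whose transcript carries the same probe sequences
      gene2 <- sprintf("GENE%04dB", s)
      spacer <- function() random_dna(sample(20:40, 1L))
      seq2 <- paste0(spacer(),
                     paste(vapply(pk$seq, function(p) paste0(p, spacer()),
                                  character(1L)), collapse = ""))
      tid2 <- new_transcript(gene2, sprintf("MUL-%03dB", s), sample(wl, 1L), seq2)
      for (j in seq_len(k)) {
        pid <- pid + 1L
        probes[[pid]] <- data.frame(probe_id = sprintf("P%05d", pid),
                                    probeset_id = setid, sequence = pk$seq[j],
                                    stringsAsFactors = FALSE)
        truth_map[[pid]] <- data.frame(probe_id = sprintf("P%05d", pid),
                                       probeset_id = setid, gene_id = gene_id,
                                       transcript_id = tid, class = cls,
                                       stringsAsFactors = FALSE)
      }
    } else if (cls == "sparse") {
      pk <- pick_probes(seq, 3L)
      for (j in seq_len(k)) {
        pid <- pid + 1L
        if (j <= 3L) {
          pseq <- pk$seq[j]; pcls <- "sparse_match"
        } else {
          pseq <- random_dna(pl); pcls <- "sparse_nonmatch"
        }
        probes[[pid]] <- data.frame(probe_id = sprintf("P%05d", pid),
                                    probeset_id = setid, sequence = pseq,
                                    stringsAsFactors = FALSE)
        truth_map[[pid]] <- data.frame(probe_id = sprintf("P%05d", pid),
                                       probeset_id = setid, gene_id = gene_id,
                                       transcript_id = tid, class = pcls,
                                       stringsAsFactors = FALSE)
      }
    }
  }

  transcripts <- Biostrings::DNAStringSet(unlist(tx_seqs))
  attrs <- do.call(rbind, attrs)
  probes <- do.call(rbind, probes)
  truth_map <- do.call(rbind, truth_map)
  rownames(attrs) <- rownames(probes) <- rownames(truth_map) <- NULL
  clean_genes <- sort(unique(truth_map$gene_id[truth_map$class == "clean"]))
  list(transcripts = transcripts, attrs = attrs, probes = probes,
       truth = list(clean_genes = clean_genes, probe_map = truth_map))
}

#' Build a probe-level expression matrix from a universe and gene profiles
#'
#' Probes whose truth target gene has a row in `gene_expr` inherit that gene's
#' profile plus probe-level noise; all other probes (decoys, non-matching
#' fillers) get pure noise around the baseline. This links the probe universe
#' to the expression simulation so the full pipeline can run probe-in.
#'
#' @param universe Output of [simulate_probe_universe()].
#' @param gene_expr Genes x samples matrix whose rownames are universe gene
#'   ids (typically the clean genes).
#' @param probe_noise_sd Probe-level measurement noise SD.
#' @param baseline Baseline intensity for unlinked probes.
#' @param seed Integer seed.
#' @return Probes x samples matrix with probe_id rownames.
#' @export
simulate_probe_matrix <- function(universe, gene_expr, probe_noise_sd = 0.25,
                                  baseline = 8, seed = 1L) {
  set.seed(seed)
  pm <- universe$truth$probe_map
  n <- ncol(gene_expr)
  out <- matrix(NA_real_, nrow = nrow(pm), ncol = n,
                dimnames = list(pm$probe_id, colnames(gene_expr)))
  for (i in seq_len(nrow(pm))) {
    g <- pm$gene_id[i]
    base <- if (g %in% rownames(gene_expr)) gene_expr[g, ] else rep(baseline, n)
    out[i, ] <- base + probe_noise_sd * stats::rnorm(n)
  }
  out
}

#' Simulate a two-group survival table
#'
#' Event times are exponential with baseline rate in the "low" group and rate
#' scaled by `hazard_ratio` in the "high" group. Censoring is by an independent
#' exponential clock whose rate is chosen so the expected censored fraction in
#' each group equals `censor_rate`.
#'
#' @param n_per_group Integer vector of length 2: samples in low / high group.
#' @param hazard_ratio Hazard ratio of high vs low group (> 0).
#' @param censor_rate Expected fraction censored, in `[0, 1)`.
#' @param seed Integer seed.
#' @param baseline_rate Baseline exponential event rate.
#' @return data.frame with columns sample, time, event (1 = event, 0 =
#'   censored), group ("low"/"high").
#' @export
simulate_survival <- function(n_per_group = c(50L, 50L), hazard_ratio = 1,
                              censor_rate = 0, seed = 1L, baseline_rate = 0.1) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1L))
  set.seed(seed)
  group <- rep(c("low", "high"), times = n_per_group)
  rate <- ifelse(group == "high", baseline_rate * hazard_ratio, baseline_rate)
  t_event <- stats::rexp(length(rate), rate = rate)
  if (censor_rate > 0) {
    c_rate <- rate * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(length(rate), rate = c_rate)
  } else {
    t_cens <- rep(Inf, length(rate))
  }
  data.frame(sample = sprintf("P%03d", seq_along(rate)),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             group = group,
             stringsAsFactors = FALSE)
}
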