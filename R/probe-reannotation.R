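#' Build an exact-match index over transcript sequences
#'
#' Wraps the transcript set and its annotation so fixed-length probe windows
#' can be looked up exactly on both strands. Coordinates are 0-based,
#' half-open, on the forward strand of the transcript. Windows containing N
#' are never matched.
#'
#' @param transcripts Named [Biostrings::DNAStringSet] or named character
#'   vector of transcript sequences (A/C/G/T/N only).
#' @param attrs data.frame with columns transcript_id, gene_id, gene_symbol,
#'   biotype covering every transcript.
#' @param probe_length Probe length the index serves (>= 8).
#' @return Object of class `transcript_index`.
#' @export
index_transcripts <- function(transcripts, attrs, probe_length = 25L) {
  probe_length <- as.integer(probe_length)
  if (probe_length < 8L) stop("probe_length must be >= 8")
  if (is.character(transcripts)) {
    bad_chr <- grepl("[^ACGTN]", transcripts)
    if (any(bad_chr)) {
      stop("transcript ", names(transcripts)[bad_chr][1L],
           " contains characters outside A/C/G/T/N")
    }
    transcripts <- Biostrings::DNAStringSet(transcripts)
  }
  if (is.null(names(transcripts)) || anyDuplicated(names(transcripts))) {
    stop("transcripts must have unique names")
  }
  bad <- Biostrings::alphabetFrequency(transcripts, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  other <- setdiff(colnames(bad), allowed)
  if (any(bad[, other, drop = FALSE] > 0)) {
    who <- names(transcripts)[rowSums(bad[, other, drop = FALSE]) > 0][1L]
    stop("transcript ", who, " contains characters outside A/C/G/T/N")
  }
  missing <- setdiff(names(transcripts), attrs$transcript_id)
  if (length(missing)) {
    stop("attribute table misses transcript(s): ", paste(missing, collapse = ", "))
  }
  gene_of <- stats::setNames(attrs$gene_id, attrs$transcript_id)
  structure(list(transcripts = transcripts, attrs = attrs,
                 gene_of = gene_of, probe_length = probe_length),
            class = "transcript_index")
}

#' Look up one fixed-length window in a transcript index
#'
#' Returns every exact occurrence of `window` on the forward strand (strand
#' "+") and every position where `window` equals the reverse complement of the
#' transcript window (strand "-"). Offsets are 0-based forward-strand
#' coordinates.
#'
#' @param index A [index_transcripts()] result.
#' @param window Character scalar of length `index$probe_length`.
#' @return data.frame with columns transcript_id, gene_id, offset, strand.
#' @export
lookup_window <- function(index, window) {
  stopifnot(inherits(index, "transcript_index"))
  if (nchar(window) != index$probe_length) {
    stop("window length ", nchar(window), " does not match index probe_length ",
         index$probe_length)
  }
  hit_one <- function(pat, strand) {
    m <- Biostrings::vmatchPattern(pat, index$transcripts, fixed = TRUE)
    starts <- Biostrings::startIndex(m)
    rows <- lapply(seq_along(starts), function(i) {
      if (is.null(starts[[i]]) || length(starts[[i]]) == 0L) return(NULL)
      tid <- names(index$transcripts)[i]
      data.frame(transcript_id = tid,
                 gene_id = unname(index$gene_of[tid]),
                 offset = starts[[i]] - 1L, strand = strand,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  fwd <- hit_one(window, "+")
  rev <- hit_one(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(window))), "-")
  out <- rbind(fwd, rev)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), gene_id = character(),
                      offset = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$transcript_id, out$offset, out$strand), , drop = FALSE]
}

#' Map probes to transcripts by exact full-length matching
#'
#' Every probe is matched exactly (no mismatches, no gaps) against both
#' strands of every transcript. A probe is "perfect" if it has at least one
#' exact full-length hit and "specific" if all its hits fall in transcripts of
#' exactly one gene.
#'
#' @param probes data.frame with columns probe_id, probeset_id, sequence; all
#'   sequences must have the index's probe length.
#' @param index A [index_transcripts()] result.
#' @return Object of class `probe_mappings`: list with `summary` (data.frame
#'   probe_id, probeset_id, n_hits, n_genes, is_perfect, is_specific) and
#'   `hits` (data.frame probe_id, transcript_id, gene_id, offset, strand).
#' @export
map_probes <- function(probes, index) {
  stopifnot(inherits(index, "transcript_index"))
  stopifnot(all(c("probe_id", "probeset_id", "sequence") %in% colnames(probes)))
  len <- nchar(probes$sequence)
  if (any(len != index$probe_length)) {
    bad <- probes$probe_id[len != index$probe_length][1L]
    stop("probe ", bad, " has length ", len[len != index$probe_length][1L],
         ", index expects ", index$probe_length)
  }
  # Probes containing N cannot match exactly; keep them with empty hit lists.
  has_n <- grepl("[^ACGT]", probes$sequence)
  hits_list <- list()
  if (any(!has_n)) {
    seqs <- Biostrings::DNAStringSet(probes$sequence[!has_n])
    names(seqs) <- probes$probe_id[!has_n]
    pd_fwd <- Biostrings::PDict(seqs)
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(seqs))
    for (i in seq_along(index$transcripts)) {
      tid <- names(index$transcripts)[i]
      subject <- index$transcripts[[i]]
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") pd_fwd else pd_rev
        m <- Biostrings::matchPDict(pd, subject)
        cnt <- S4Vectors::elementNROWS(m)
        idx <- which(cnt > 0L)
        for (j in idx) {
          hits_list[[length(hits_list) + 1L]] <- data.frame(
            probe_id = names(seqs)[j], transcript_id = tid,
            gene_id = unname(index$gene_of[tid]),
            offset = S4Vectors::start(m[[j]]) - 1L, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hits_list)) do.call(rbind, hits_list) else
    data.frame(probe_id = character(), transcript_id = character(),
               gene_id = character(), offset = integer(), strand = character(),
               stringsAsFactors = FALSE)
  n_hits <- table(factor(hits$probe_id, levels = probes$probe_id))
  n_genes <- vapply(probes$probe_id, function(p) {
    length(unique(hits$gene_id[hits$probe_id == p]))
  }, integer(1L))
  summary <- data.frame(probe_id = probes$probe_id,
                        probeset_id = probes$probeset_id,
                        n_hits = as.integer(n_hits),
                        n_genes = n_genes,
                        is_perfect = as.integer(n_hits) > 0L,
                        is_specific = n_genes == 1L,
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(summary = summary, hits = hits), class = "probe_mappings")
}

#' Filter probe mappings into an lncRNA annotation table
#'
#' A gene is retained iff (a) it is supported by at least `min_probes`
#' distinct probes that (b) match perfectly and (c) match specifically (all of
#' a probe's hits in that one gene), and its biotype is on the lncRNA
#' whitelist. Probe-set boundaries are ignored: the probe count is per gene.
#'
#' @param mappings A [map_probes()] result.
#' @param attrs Transcript attribute data.frame (transcript_id, gene_id,
#'   gene_symbol, biotype).
#' @param whitelist Biotypes accepted as lncRNA; default [lncrna_biotypes()].
#' @param min_probes Minimum qualifying probes per gene (default 4).
#' @return data.frame (class `lncrna_annotation`) with columns gene_id,
#'   gene_symbol, biotype, probe_ids (comma-separated), n_probes; sorted by
#'   gene_id.
#' @export
filter_mappings <- function(mappings, attrs, whitelist = lncrna_biotypes(),
                            min_probes = 4L) {
  stopifnot(inherits(mappings, "probe_mappings"))
  empty <- data.frame(gene_id = character(), gene_symbol = character(),
                      biotype = character(), probe_ids = character(),
                      n_probes = integer(), stringsAsFactors = FALSE)
  qual <- mappings$summary$probe_id[mappings$summary$is_perfect &
                                      mappings$summary$is_specific]
  if (length(qual) == 0L) return(structure(empty, class = c("lncrna_annotation", "data.frame")))
  hits <- mappings$hits[mappings$hits$probe_id %in% qual, , drop = FALSE]
  # one gene per qualifying probe by definition of specific
  pg <- unique(hits[, c("probe_id", "gene_id")])
  counts <- tapply(pg$probe_id, pg$gene_id, function(p) sort(unique(p)),
                   simplify = FALSE)
  gene_meta <- attrs[!duplicated(attrs$gene_id),
                     c("gene_id", "gene_symbol", "biotype")]
  rows <- lapply(names(counts), function(g) {
    ps <- counts[[g]]
    meta <- gene_meta[gene_meta$gene_id == g, , drop = FALSE]
    if (length(ps) < min_probes) return(NULL)
    if (!meta$biotype %in% whitelist) return(NULL)
    data.frame(gene_id = g, gene_symbol = meta$gene_symbol,
               biotype = meta$biotype,
               probe_ids = paste(ps, collapse = ","),
               n_probes = length(ps), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("lncrna_annotation", "data.frame"))
}

#' Aggregate a probe-level matrix to lncRNA level
#'
#' Each retained gene's expression is the arithmetic mean of its supporting
#' probe rows, per sample; a single-probe gene copies its probe row.
#'
#' @param probe_matrix Probes x samples numeric matrix with probe_id rownames.
#' @param annotation A [filter_mappings()] table.
#' @return Genes x samples matrix with gene_id rownames, sample order
#'   preserved.
#' @export
aggregate_to_lncrna <- function(probe_matrix, annotation) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  probe_sets <- strsplit(annotation$probe_ids, ",", fixed = TRUE)
  missing <- setdiff(unlist(probe_sets), rownames(probe_matrix))
  if (length(missing)) {
    stop("probe id(s) absent from probe matrix: ", paste(missing, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = nrow(annotation), ncol = ncol(probe_matrix),
                dimnames = list(annotation$gene_id, colnames(probe_matrix)))
  for (i in seq_len(nrow(annotation))) {
    out[i, ] <- colMeans(probe_matrix[probe_sets[[i]], , drop = FALSE])
  }
  out
}
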