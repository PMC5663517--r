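# Reading site/label inputs and genome sequence; writing all model outputs
# (weight tables, MEME minimal motifs, hill BED, score matrices, run logs).

#' Load genomic sites and extract labeled windows
#'
#' Reads a site table (TSV with header; columns `chrom`, `start`, optional
#' `end`, and `labels` with semicolon-separated labels) and a genome FASTA,
#' expands each site's midpoint to a fixed window `[mid - window/2,
#' mid + window/2)` in 0-based half-open coordinates, and builds a
#' [labeled_dataset()]. Windows that exceed chromosome bounds or contain more
#' than 10% N are dropped with a message. Strand is ignored: features are
#' strand-symmetric through canonical k-mers.
#'
#' @param path site table path.
#' @param genome genome FASTA path.
#' @param window window width in bp (even; default 150).
#' @return a [labeled_dataset()]; the kept site rows are recorded in
#'   attribute `"sites"`.
#' @export
load_sites <- function(path, genome, window = 150L) {
  stopifnot(window %% 2L == 0L)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("site table is empty")
  need <- c("chrom", "start", "labels")
  if (!all(need %in% names(tab)))
    stop("site table needs columns: ", paste(need, collapse = ", "))
  empty <- which(is.na(tab$labels) | trimws(tab$labels) == "")
  if (length(empty))
    stop("empty label field at line ", empty[1L] + 1L)

  gen <- Biostrings::readDNAStringSet(genome)
  names(gen) <- sub("\\s.*$", "", names(gen))
  missing_chr <- setdiff(unique(tab$chrom), names(gen))
  if (length(missing_chr))
    stop("chromosome not in genome: ", paste(missing_chr, collapse = ", "))

  mid <- if ("end" %in% names(tab) && !all(is.na(tab$end)))
    (tab$start + tab$end) %/% 2L else tab$start
  ws <- mid - window %/% 2L
  we <- ws + window
  chrlen <- Biostrings::width(gen)[match(tab$chrom, names(gen))]
  ok <- ws >= 0L & we <= chrlen
  seqs <- rep(NA_character_, nrow(tab))
  if (any(ok))
    seqs[ok] <- as.character(Biostrings::subseq(gen[tab$chrom[ok]],
                                                start = ws[ok] + 1L,
                                                end = we[ok]))
  n_frac <- vapply(seqs, function(s)
    if (is.na(s)) 1 else mean(strsplit(s, "")[[1]] == "N"), numeric(1))
  keep <- ok & n_frac <= 0.10
  if (any(!keep))
    message("dropped ", sum(!keep),
            " site(s): window out of bounds or >10% N")
  if (!any(keep)) stop("no usable sites after filtering")

  label_sets <- strsplit(tab$labels[keep], ";", fixed = TRUE)
  ids <- sprintf("%s:%d-%d", tab$chrom[keep], as.integer(ws[keep]),
                 as.integer(we[keep]))
  ds <- labeled_dataset(unname(seqs[keep]), label_sets, ids = ids)
  attr(ds, "sites") <- data.frame(chrom = tab$chrom[keep],
                                  start = ws[keep], end = we[keep],
                                  stringsAsFactors = FALSE)
  ds
}

#' Load pre-extracted labeled sequences from FASTA
#'
#' Labels are carried in headers after a `|`, semicolon-separated, e.g.
#' `>site1|early;proximal`.
#'
#' @param path FASTA path.
#' @return a [labeled_dataset()].
#' @export
load_labeled_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("FASTA headers must carry labels after '|'")
  labels <- strsplit(vapply(parts, `[`, character(1), 2L), ";", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  labeled_dataset(as.character(seqs), labels, ids = ids)
}

#' Write motifs in MEME minimal format
#'
#' @param motifs list of [pwm()] (may be empty: a valid header is still
#'   written).
#' @param path output file.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(m$matrix)), con)
    utils::write.table(format(m$matrix, digits = 6), con,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' @param path MEME minimal file.
#' @return named list of [pwm()].
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s", lines[i])) {
      name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2L]
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      mat <- do.call(rbind, lapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
      mat <- mat / rowSums(mat)
      out[[name]] <- pwm(mat, name = name)
      i <- j + w + 1L
    } else i <- i + 1L
  }
  out
}

#' Clamp scores to the plotting saturation range
#'
#' Heat-map displays of motif-label scores use a shared colour scale
#' saturating at -0.4 and +0.4; this clamps values to that range.
#'
#' @param x numeric scores.
#' @param limit saturation magnitude (default 0.4).
#' @return clamped scores.
#' @export
saturate_scores <- function(x, limit = 0.4) {
  pmin(pmax(x, -limit), limit)
}

#' Write hills as BED
#'
#' Sequence-relative coordinates, or genome-relative when the dataset carries
#' site coordinates (from [load_sites()]).
#'
#' @param hills hill data.frame (possibly row-bound over labels).
#' @param path output BED path.
#' @param sites optional data.frame of site coordinates (chrom/start/end per
#'   sequence index).
#' @export
write_hills_bed <- function(hills, path, sites = NULL) {
  if (is.null(sites)) {
    bed <- data.frame(hills$seq_id, hills$start, hills$end,
                      hills$source_model, round(hills$score, 4))
  } else {
    bed <- data.frame(sites$chrom[hills$seq_index],
                      sites$start[hills$seq_index] + hills$start,
                      sites$start[hills$seq_index] + hills$end,
                      hills$source_model, round(hills$score, 4))
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write all model outputs
#'
#' Writes per-label and per-subclass k-mer weight tables (TSV), discovered
#' motifs (MEME minimal format), the motif x label/subclass score matrix
#' (TSV; for plotting, scores are conventionally clamped at a colour
#' saturation of +/-0.4, see [saturate_scores()]), hills (BED), and a JSON
#' run log with the training configuration.
#'
#' @param model an `md_model`.
#' @param motifs a `motif_score_table` (or `NULL`).
#' @param outdir output directory (created if needed).
#' @param sites optional site coordinates for genome-relative hill BED.
#' @return invisibly, the vector of files written.
#' @export
write_outputs <- function(model, motifs, outdir, sites = NULL) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  files <- character(0)

  f <- file.path(outdir, "label_weights.tsv")
  utils::write.table(
    data.frame(kmer = model$space$columns, t(model$weights$W_lab),
               check.names = FALSE),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(outdir, "subclass_weights.tsv")
  utils::write.table(
    data.frame(feature = colnames(model$weights$W_sub),
               t(model$weights$W_sub), check.names = FALSE),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  if (!is.null(motifs)) {
    f <- file.path(outdir, "motifs.meme.txt")
    write_meme(motifs$motifs, f)
    files <- c(files, f)
    f <- file.path(outdir, "motif_scores.tsv")
    utils::write.table(
      data.frame(motif = rownames(motifs$scores), motifs$scores,
                 check.names = FALSE),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    if (!is.null(motifs$hills)) {
      f <- file.path(outdir, "hills.bed")
      write_hills_bed(do.call(rbind, motifs$hills), f, sites = sites)
      files <- c(files, f)
    }
  }

  f <- file.path(outdir, "training_log.tsv")
  n_sweeps <- length(model$objective)
  utils::write.table(
    data.frame(sweep = seq_len(n_sweeps),
               objective = model$objective,
               admm_iters = model$admm_iters[seq_len(n_sweeps)],
               primal_residual = vapply(model$residuals[seq_len(n_sweeps)],
                                        function(r) utils::tail(r$primal, 1),
                                        numeric(1)),
               dual_residual = vapply(model$residuals[seq_len(n_sweeps)],
                                      function(r) utils::tail(r$dual, 1),
                                      numeric(1))),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(outdir, "run_log.json")
  cfg <- model$config
  cfg$lambda_grid <- as.numeric(cfg$lambda_grid)
  jsonlite::write_json(
    list(config = unclass(cfg), labels = model$labels,
         subclasses = model$subclasses,
         objective = model$objective, admm_iters = model$admm_iters),
    f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Read a weight table written by [write_outputs()]
#'
#' @param path TSV path.
#' @return numeric matrix (models x features).
#' @export
read_weight_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- t(as.matrix(tab[, -1L, drop = FALSE]))
  colnames(m) <- tab[[1L]]
  m
}
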