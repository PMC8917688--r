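#' Read an assembly FASTA file
#'
#' Contigs are returned as a data frame with one row per record, in file
#' order. Sequences are uppercased and any character outside `{A,C,G,T,N}`
#' (IUPAC ambiguity codes, gaps) is coerced to `N`; a warning reports how
#' many characters were coerced.
#'
#' @param path Path to a FASTA file of DNA contigs.
#' @return A data frame with columns `contig_id`, `description` (possibly
#'   empty string) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop_format("FASTA record with empty header")
  if (anyDuplicated(ids)) {
    stop_format(sprintf("duplicate contig id in FASTA: %s",
                        ids[duplicated(ids)][1L]))
  }
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop_format(sprintf("FASTA record '%s' has an empty sequence",
                        ids[empty][1L]))
  }
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", seqs), function(m)
    if (m[1L] == -1L) 0L else length(m), integer(1)))
  if (n_bad > 0L) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(sprintf("%d non-ACGTN character(s) coerced to N", n_bad),
            call. = FALSE)
  }
  data.frame(contig_id = unname(ids), description = unname(desc),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write contigs to a FASTA file
#'
#' @param contigs Data frame as returned by [read_fasta()] (columns
#'   `contig_id`, `sequence`, optional `description`).
#' @param path Output path.
#' @param line_width Body line width in characters (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(contigs, path, line_width = 70L) {
  if (!is.numeric(line_width) || line_width < 1) {
    stop_param("line_width must be a positive integer")
  }
  desc <- if ("description" %in% names(contigs)) contigs$description else
    rep("", nrow(contigs))
  if (nrow(contigs) == 0L) {
    ok <- file.create(path)
    if (!ok) stop_input(sprintf("cannot write to %s", path))
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(contigs$sequence)
  names(set) <- ifelse(nzchar(desc),
                       paste(contigs$contig_id, desc),
                       contigs$contig_id)
  tryCatch(
    Biostrings::writeXStringSet(set, filepath = path,
                                width = as.integer(line_width)),
    error = function(e) stop_input(sprintf("cannot write to %s: %s",
                                           path, conditionMessage(e))))
  invisible(path)
}

#' Break long contigs into fixed-size fragments
#'
#' Emulates the fragmentation seen in metagenomic assemblies: contigs
#' strictly longer than `length_threshold` are split left-to-right into
#' consecutive `fragment_size` pieces plus a final remainder piece; shorter
#' contigs pass through unchanged. Concatenating a contig's fragments in
#' order reproduces the original sequence exactly.
#'
#' @param contigs Contig data frame ([read_fasta()] layout).
#' @param length_threshold Only contigs longer than this are split
#'   (default 1e6 bp; strict `>`).
#' @param fragment_size Fragment length in bp (default 1e5).
#' @return A contig data frame; fragment ids are
#'   `<original id>_frag<1-based index>`.
#' @export
fragment_contigs <- function(contigs, length_threshold = 1e6,
                             fragment_size = 1e5) {
  if (fragment_size <= 0 || length_threshold <= 0) {
    stop_param("length_threshold and fragment_size must be positive")
  }
  if (fragment_size > length_threshold) {
    stop_param("fragment_size must not exceed length_threshold")
  }
  if (!"description" %in% names(contigs)) contigs$description <- ""
  contigs <- contigs[, c("contig_id", "description", "sequence")]
  out <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    len <- nchar(contigs$sequence[i])
    if (len <= length_threshold) {
      out[[i]] <- contigs[i, , drop = FALSE]
      next
    }
    starts <- seq.int(1L, len, by = fragment_size)
    ends <- pmin(starts + fragment_size - 1L, len)
    out[[i]] <- data.frame(
      contig_id = paste0(contigs$contig_id[i], "_frag", seq_along(starts)),
      description = rep(contigs$description[i], length(starts)),
      sequence = substring(contigs$sequence[i], starts, ends),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parse a per-contig read-depth table
#'
#' Reads the tab-separated summary dialect produced by MetaBAT's
#' `jgi_summarize_bam_contig_depths` (header with at least `contigName`,
#' `contigLen`, `totalAvgDepth`; extra per-sample columns ignored, column
#' order free).
#'
#' @param path Path to the depth TSV.
#' @return A named numeric vector, contig id -> mean depth.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("depth table not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("contigName", "totalAvgDepth")) {
    if (!col %in% names(tab)) {
      stop_format(sprintf("depth table is missing required column '%s'", col))
    }
  }
  if (nrow(tab) == 0L) return(stats::setNames(numeric(0), character(0)))
  depth <- suppressWarnings(as.numeric(tab$totalAvgDepth))
  if (anyNA(depth)) {
    # +1 for the header row
    stop_format(sprintf("non-numeric totalAvgDepth at line %d",
                        which(is.na(depth))[1L] + 1L))
  }
  if (any(depth < 0)) stop_format("negative depth in depth table")
  stats::setNames(depth, as.character(tab$contigName))
}
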