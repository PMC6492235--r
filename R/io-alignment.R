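#' Read a protein alignment from FASTA or relaxed PHYLIP
#'
#' FASTA records or relaxed (whitespace-separated) sequential PHYLIP rows
#' are case-normalized to upper case and validated against the 22-symbol
#' alphabet (20 residues, gap `-`, unknown `X`).
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"phylip"`.
#' @return A [ProteinAlignment-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACDEF", ">b", "ACDEG"), f)
#' readAlignment(f)
#' @export
readAlignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    if (!length(ss)) stop("no FASTA records in ", path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- as.character(ss)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(head_tok) < 2L || anyNA(suppressWarnings(as.integer(head_tok[1:2]))))
      stop("malformed PHYLIP header in ", path)
    ntax <- as.integer(head_tok[1]); nsite <- as.integer(head_tok[2])
    body <- lines[-1]
    if (length(body) < ntax)
      stop("PHYLIP file declares ", ntax, " taxa but has ", length(body), " rows")
    ids <- character(ntax); seqs <- character(ntax)
    for (i in seq_len(ntax)) {
      tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
      ids[i] <- tok[1]
      seqs[i] <- paste(tok[-1], collapse = "")
    }
    if (any(nchar(seqs) != nsite))
      stop(sprintf(
        "alignment-length error: PHYLIP header declares %d sites but row '%s' has %d",
        nsite, ids[which(nchar(seqs) != nsite)[1]],
        nchar(seqs)[which(nchar(seqs) != nsite)[1]]))
  }
  ProteinAlignment(ids, seqs)
}

#' Write a protein alignment
#'
#' @param x a [ProteinAlignment-class].
#' @param path output file.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential).
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(x, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", x@ids), x@seqs))
  } else {
    out <- c(sprintf("%d %d", nSequences(x), nSites(x)),
             paste(x@ids, x@seqs))
  }
  writeLines(out, path)
  invisible(path)
}
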