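#' @keywords internal
"_PACKAGE"

RNA_ALPHABET <- c("A", "C", "G", "U")

#' RNA window set
#'
#' A validated collection of fixed-length RNA windows with optional binary
#' labels. All records must share one length and use only the residues
#' A, C, G, U (T is accepted on input and mapped to U; lowercase is
#' uppercased).
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of residue strings, same length as `id`.
#' @param label optional integer vector of 0/1 labels (NA allowed).
#'
#' @return An object of class `rna_set`: a list with elements `id`, `seq`,
#'   `label`, `n` (common window length) and `m` (number of records).
#' @export
rna_set <- function(id, seq, label = NULL) {
  stopifnot(length(id) == length(seq))
  seq <- toupper(seq)
  seq <- gsub("T", "U", seq, fixed = TRUE)
  if (anyDuplicated(id)) stop("duplicate sequence ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  bad <- grepl(paste0("[^", paste(RNA_ALPHABET, collapse = ""), "]"), seq)
  if (any(bad)) {
    off <- id[which(bad)[1]]
    sym <- gsub("[ACGU]", "", seq[which(bad)[1]])
    stop("record '", off, "' contains invalid symbol(s): ",
         paste(unique(strsplit(sym, "")[[1]]), collapse = ", "))
  }
  lens <- nchar(seq)
  if (length(unique(lens)) > 1L) {
    stop("sequences must share one length; lengths found: ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  if (is.null(label)) label <- rep(NA_integer_, length(id))
  label <- as.integer(as.vector(label))
  if (!all(is.na(label) | label %in% c(0L, 1L))) {
    stop("labels must be 0, 1 or NA")
  }
  structure(list(id = unname(as.character(id)), seq = unname(seq),
                 label = unname(label),
                 n = unique(lens), m = length(id)),
            class = "rna_set")
}

#' @export
print.rna_set <- function(x, ...) {
  nl <- sum(!is.na(x$label))
  cat("rna_set:", x$m, "windows of length", x$n,
      sprintf("(%d labelled, %d positive)\n", nl, sum(x$label == 1L, na.rm = TRUE)))
  invisible(x)
}

#' @export
length.rna_set <- function(x) x$m

#' @export
`[.rna_set` <- function(x, i) {
  rna_set(x$id[i], x$seq[i], x$label[i])
}

#' Read fixed-length RNA windows from FASTA
#'
#' Parses a (possibly wrapped) FASTA file of equal-length RNA windows.
#' Labels may be carried in headers as a `label=0|1` token, or supplied as
#' a two-column tab-separated file (id, label) via `labels`.
#'
#' @param path path to the FASTA file.
#' @param labels optional path to a two-column TSV (id, label) with no
#'   header. Overrides header tags.
#' @param invalid what to do with records containing symbols outside
#'   A/C/G/U/T: `"error"` (default) aborts naming the record, `"drop"`
#'   removes them with a warning.
#'
#' @return An [rna_set].
#' @export
read_rna_windows <- function(path, labels = NULL,
                             invalid = c("error", "drop")) {
  invalid <- match.arg(invalid)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  headers <- names(ss)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)

  lab <- rep(NA_integer_, length(ids))
  tag <- regmatches(headers, regexpr("label=[01]", headers))
  has_tag <- grepl("label=[01]", headers)
  lab[has_tag] <- as.integer(sub("label=", "",
                                 regmatches(headers,
                                            regexpr("label=[01]", headers))))
  if (!is.null(labels)) {
    tab <- utils::read.table(labels, sep = "\t", header = FALSE,
                             col.names = c("id", "label"),
                             colClasses = c("character", "integer"))
    idx <- match(ids, tab$id)
    if (anyNA(idx)) stop("label file missing ids: ",
                         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    lab <- tab$label[idx]
  }

  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    if (invalid == "error") {
      sym <- unique(strsplit(gsub("[ACGU]", "", seqs[which(bad)[1]]), "")[[1]])
      stop("record '", ids[which(bad)[1]], "' contains invalid symbol(s): ",
           paste(sym, collapse = ", "))
    }
    warning("dropping ", sum(bad), " record(s) with non-ACGU symbols")
    ids <- ids[!bad]; seqs <- seqs[!bad]; lab <- lab[!bad]
  }
  rna_set(ids, seqs, lab)
}

#' Write an rna_set to FASTA (and optional labels TSV)
#'
#' Headers carry labels as `label=0|1` tokens in the dialect
#' [read_rna_windows()] consumes.
#'
#' @param x an [rna_set].
#' @param path output FASTA path.
#' @param labels optional path for a two-column (id, label) TSV.
#' @return `path`, invisibly.
#' @export
write_rna_windows <- function(x, path, labels = NULL) {
  stopifnot(inherits(x, "rna_set"))
  hdr <- ifelse(is.na(x$label), x$id, paste0(x$id, " label=", x$label))
  writeLines(paste0(">", hdr, "\n", x$seq), path)
  if (!is.null(labels)) {
    utils::write.table(data.frame(x$id, x$label), labels, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' K-mer vocabulary in lexicographic order
#'
#' All length-`K` words over the RNA alphabet with A < C < G < U, in
#' lexicographic order (AAA, AAC, ..., UUU for K = 3). This order fixes
#' the column indexing of every k-mer feature matrix the package writes.
#'
#' @param K word length (default 3).
#' @return Character vector of length `4^K`.
#' @export
kmer_vocab <- function(K = 3) {
  stopifnot(K >= 1)
  g <- do.call(expand.grid,
               c(rep(list(RNA_ALPHABET), K), stringsAsFactors = FALSE))
  do.call(paste0, rev(g))
}

seq_to_codes <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1]], RNA_ALPHABET) - 1L
}

#' Tokenize a sequence into overlapping 3-mer indices
#'
#' Returns the stream of overlapping 3-mer token indices (0-based, in
#' `[0, 63]`) at offsets `l = 0 ... n-3`, using the same lexicographic
#' order as [kmer_vocab()]: token `16 a + 4 b + c` for residues with codes
#' A=0, C=1, G=2, U=3.
#'
#' @param x an [rna_set] or character vector of sequences.
#' @return Integer matrix, one row per sequence, `n - 2` columns.
#' @export
tokenize <- function(x) {
  seqs <- if (inherits(x, "rna_set")) x$seq else toupper(gsub("T", "U", x))
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("sequences must share one length")
  if (n < 3L) stop("sequences shorter than 3 cannot be tokenized")
  t(vapply(seqs, function(s) {
    a <- seq_to_codes(s)
    L <- length(a) - 2L
    16L * a[1:L] + 4L * a[2:(L + 1L)] + a[3:(L + 2L)]
  }, integer(n - 2L), USE.NAMES = FALSE))
}

#' Normalized 3-mer frequency encoding
#'
#' Counts the overlapping length-`K` words of each sequence and divides by
#' the number of windows (`n - K + 1`), so every row sums to 1. Columns
#' follow [kmer_vocab()] order.
#'
#' @param x an [rna_set] or character vector of sequences.
#' @param K word length (default 3).
#' @return Numeric matrix, one row per sequence, `4^K` columns named by
#'   the k-mer vocabulary.
#' @export
kmer_encode <- function(x, K = 3) {
  seqs <- if (inherits(x, "rna_set")) x$seq else toupper(gsub("T", "U", x))
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("sequences must share one length")
  if (n < K) stop("sequences shorter than K = ", K)
  voc <- kmer_vocab(K)
  nw <- n - K + 1L
  pow <- 4L^((K - 1L):0L)
  M <- t(vapply(seqs, function(s) {
    a <- seq_to_codes(s)
    idx <- rep(0L, nw)
    for (j in seq_len(K)) idx <- idx + pow[j] * a[j:(j + nw - 1L)]
    tabulate(idx + 1L, nbins = length(voc)) / nw
  }, numeric(length(voc)), USE.NAMES = FALSE))
  colnames(M) <- voc
  if (inherits(x, "rna_set")) rownames(M) <- x$id
  M
}
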