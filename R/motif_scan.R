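# IUPAC degenerate-base dictionary (DNA)
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

new_pwm <- function(mat, id, consensus = NULL) {
  if (!is.matrix(mat) || nrow(mat) != 4)
    rxa_abort("a PWM must be a 4 x L matrix (rows A, C, G, T)")
  if (ncol(mat) < 1) rxa_abort("a PWM needs at least one position")
  if (any(mat < 0)) rxa_abort("PWM weights must be non-negative")
  if (any(apply(mat, 2, max) <= 0))
    rxa_abort("every PWM position needs a positive maximum weight")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(matrix = mat, id = id, consensus = consensus),
            class = "PWM")
}

#' Build a 0/1 position weight matrix from an IUPAC consensus
#'
#' Each position gets weight 1 for every base the IUPAC code allows and 0
#' otherwise, so a window's score counts matching positions and the maximal
#' score equals the motif length. This is the default matrix when no
#' numeric PWM is supplied.
#'
#' @param iupac Consensus string, e.g. `"ACYGGTTT"`.
#' @param id Motif label (defaults to the consensus itself).
#' @return Object of class `PWM`: list with `matrix` (4 x L, rows A/C/G/T),
#'   `id`, `consensus`.
#' @export
pwm_from_consensus <- function(iupac, id = iupac) {
  chars <- strsplit(toupper(iupac), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_DNA))
  if (length(bad))
    rxa_abort("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  mat <- vapply(chars, function(ch) {
    col <- numeric(4); names(col) <- c("A", "C", "G", "T")
    col[IUPAC_DNA[[ch]]] <- 1
    col
  }, numeric(4))
  new_pwm(matrix(mat, nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL)),
          id = id, consensus = toupper(iupac))
}

#' Reverse complement of a PWM
#'
#' Reverses the positions and swaps complementary base rows; the consensus
#' label (if any) is reverse-complemented with IUPAC algebra.
#'
#' @param pwm A `PWM`.
#' @return The reverse-complement `PWM`.
#' @export
pwm_reverse_complement <- function(pwm) {
  m <- pwm$matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$matrix))),
                  drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  cons <- if (!is.null(pwm$consensus))
    paste(rev(IUPAC_COMPLEMENT[strsplit(pwm$consensus, "")[[1]]]),
          collapse = "")
  new_pwm(m, id = paste0(pwm$id, "_rc"), consensus = cons)
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s' (L = %d)%s\n", x$id, ncol(x$matrix),
              if (!is.null(x$consensus)) paste0(", consensus ", x$consensus)
              else ""))
  print(x$matrix)
  invisible(x)
}

#' Read a PWM from text
#'
#' Accepts either a TRANSFAC-style block (a `P0 A C G T` header line with
#' numbered rows) or a plain whitespace-delimited table with columns
#' A, C, G, T (header optional), one row per motif position.
#'
#' @param path Path to the matrix file.
#' @param id Motif label (defaults to the file name, or the TRANSFAC `ID`).
#' @return A `PWM`.
#' @export
read_pwm <- function(path, id = NULL) {
  if (!file.exists(path)) rxa_abort("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  p0 <- grep("^P[0O]\\b", lines)
  if (length(p0)) {
    idl <- grep("^ID\\b", lines, value = TRUE)
    if (is.null(id) && length(idl)) id <- trimws(sub("^ID", "", idl[1]))
    cols <- toupper(strsplit(lines[p0[1]], "\\s+")[[1]][-1])[1:4]
    body <- lines[-seq_len(p0[1])]
    body <- body[grepl("^[0-9]", body)]
    rows <- lapply(strsplit(body, "\\s+"), function(x)
      suppressWarnings(as.numeric(x[2:5])))
  } else {
    maybe_header <- grepl("^[ACGTacgt[:space:]]+$", lines[1]) &&
      !grepl("[0-9.]", lines[1])
    cols <- if (maybe_header)
      toupper(strsplit(lines[1], "\\s+")[[1]])[1:4] else c("A", "C", "G", "T")
    body <- if (maybe_header) lines[-1] else lines
    rows <- lapply(strsplit(body, "\\s+"), function(x)
      suppressWarnings(as.numeric(x[1:4])))
  }
  if (!length(rows) || anyNA(unlist(rows)))
    rxa_abort("malformed PWM file: ", path)
  m <- t(do.call(rbind, rows))
  rownames(m) <- cols
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  new_pwm(m, id = id %||% sub("\\.[^.]*$", "", basename(path)))
}

# additive window scores of one strand; codes: 1..4 = ACGT, 5 = N (weight 0)
pwm_window_scores <- function(codes, mat) {
  L <- ncol(mat); n <- length(codes)
  nwin <- n - L + 1L
  if (nwin < 1L) return(numeric(0))
  W <- rbind(mat, 0)  # row 5: N contributes 0
  s <- numeric(nwin)
  for (j in seq_len(L)) s <- s + W[cbind(codes[j:(j + nwin - 1L)], j)]
  s
}

#' Scan a DNA sequence with a PWM
#'
#' Slides the matrix along the sequence and emits every window whose
#' additive score reaches `threshold_frac` of the maximal achievable score
#' (default 85%, the conventional match threshold). With
#' `both_strands = TRUE` the reverse-complement matrix is scanned as well;
#' minus-strand hits are reported in forward coordinates. `N` bases score 0
#' at their position. Coordinates are 0-based, half-open.
#'
#' @param seq DNA string over A/C/G/T/N (case-insensitive).
#' @param pwm A `PWM`.
#' @param threshold_frac Score threshold as a fraction of the maximum, in
#'   (0, 1] (values above 1 simply yield no hits).
#' @param both_strands Scan the reverse-complement orientation too?
#' @param seq_id Sequence label for the output.
#' @return data.frame of class `MotifHits`: `sequence_id`, `start`, `end`,
#'   `strand`, `score`, `frac_of_max`, `motif_id`, sorted by `start`.
#' @export
scan_pwm <- function(seq, pwm, threshold_frac = 0.85, both_strands = TRUE,
                     seq_id = "seq") {
  if (threshold_frac <= 0) rxa_abort("`threshold_frac` must be positive")
  seq <- toupper(as.character(seq))
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T", "N"))
  if (anyNA(codes)) rxa_abort("sequence contains characters outside A/C/G/T/N")
  L <- ncol(pwm$matrix)
  max_score <- sum(apply(pwm$matrix, 2, max))
  thr <- threshold_frac * max_score - 1e-9
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), frac_of_max = numeric(),
                      motif_id = character(), stringsAsFactors = FALSE)
  class(empty) <- c("MotifHits", "data.frame")
  if (length(codes) < L) return(empty)
  hits <- list(empty)
  strands <- if (both_strands) c("+", "-") else "+"
  for (st in strands) {
    mat <- if (st == "+") pwm$matrix else pwm_reverse_complement(pwm)$matrix
    s <- pwm_window_scores(codes, mat)
    at <- which(s >= thr)
    if (length(at))
      hits[[length(hits) + 1L]] <- data.frame(
        sequence_id = seq_id, start = at - 1L, end = at - 1L + L,
        strand = st, score = s[at], frac_of_max = s[at] / max_score,
        motif_id = pwm$id, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MotifHits", "data.frame")
  out
}

#' Scan a promoter FASTA with a PWM
#'
#' Applies [scan_pwm()] to every record of a FASTA file (e.g. pre-extracted
#' 2-kbp 5' upstream sequences) and concatenates the hits. FASTA record
#' names are truncated at the first whitespace.
#'
#' @param fasta Path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @param pwm A `PWM`.
#' @param threshold_frac,both_strands Passed to [scan_pwm()].
#' @return A `MotifHits` data.frame over all sequences.
#' @export
scan_promoters <- function(fasta, pwm, threshold_frac = 0.85,
                           both_strands = TRUE) {
  seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta)
          else fasta
  ids <- sub("\\s.*$", "", names(seqs))
  out <- do.call(rbind, lapply(seq_along(seqs), function(i)
    scan_pwm(as.character(seqs[[i]]), pwm, threshold_frac, both_strands,
             seq_id = ids[i])))
  class(out) <- c("MotifHits", "data.frame")
  out
}

#' Collapse duplicate hits from overlapping transcripts
#'
#' When the same promoter region is scanned once per transcript, identical
#' hits recur; hits identical in (sequence_id, start, strand) are collapsed
#' to one. Opposite-strand hits at the same position are both retained.
#'
#' @param hits A `MotifHits` data.frame.
#' @return De-duplicated `MotifHits`.
#' @export
dedup_hits <- function(hits) {
  out <- hits[!duplicated(hits[, c("sequence_id", "start", "strand")]), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write motif hits as BED6
#'
#' Columns: sequence_id, start, end, motif_id, score (frac_of_max scaled to
#' 0-1000), strand. Coordinates stay 0-based half-open as in BED.
#'
#' @param hits A `MotifHits` data.frame.
#' @param path Output path.
#' @export
write_bed <- function(hits, path) {
  bed <- data.frame(hits$sequence_id, hits$start, hits$end, hits$motif_id,
                    pmin(1000L, as.integer(round(hits$frac_of_max * 1000))),
                    hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
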