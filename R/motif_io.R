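# Readers and writers for the three standard motif matrix formats used by
# motif-TF databases: TRANSFAC-style matrices, MEME minimal format and
# JASPAR position frequency matrices. All three map onto the W x 4
# count matrix of `nucleotide_motif`.

.parse_error <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

#' Read motifs from a file
#'
#' @param path file path.
#' @param format one of `"transfac"`, `"meme"`, `"jaspar"`.
#' @return list of [nucleotide_motif] in file order.
#' @export
read_motifs <- function(path, format = c("transfac", "meme", "jaspar")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  switch(format,
         transfac = .read_transfac(lines, path),
         meme     = .read_meme(lines, path),
         jaspar   = .read_jaspar(lines, path))
}

#' Write motifs to a file
#'
#' The output is re-readable by [read_motifs] with the same format, and
#' writing the re-read motifs again reproduces the file byte for byte.
#'
#' @param motifs list of [nucleotide_motif].
#' @param path output file path.
#' @param format one of `"transfac"`, `"meme"`, `"jaspar"`.
#' @export
write_motifs <- function(motifs, path, format = c("transfac", "meme", "jaspar")) {
  format <- match.arg(format)
  lines <- switch(format,
                  transfac = unlist(lapply(motifs, .format_transfac)),
                  meme     = .format_meme(motifs),
                  jaspar   = unlist(lapply(motifs, .format_jaspar)))
  if (is.null(lines)) lines <- character()
  con <- file(path, "wb")  # fixed newline convention => byte-stable
  on.exit(close(con))
  writeLines(lines, con)
  invisible(NULL)
}

.num <- function(x) formatC(x, format = "fg", digits = 10, width = 1)

## ---- TRANSFAC ----------------------------------------------------------

.read_transfac <- function(lines, path) {
  motifs <- list()
  id <- NA_character_; de <- NULL; rows <- list(); in_matrix <- FALSE
  flush <- function(lineno) {
    if (is.na(id) && length(rows) == 0L) return(invisible())
    if (is.na(id)) .parse_error(path, lineno, "matrix stanza without AC/ID")
    if (length(rows) == 0L) .parse_error(path, lineno, "motif without matrix rows")
    motifs[[length(motifs) + 1L]] <<-
      nucleotide_motif(id, do.call(rbind, rows), description = de)
    id <<- NA_character_; de <<- NULL; rows <<- list(); in_matrix <<- FALSE
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^//", ln)) { flush(i); next }
    if (grepl("^(AC|ID)\\s", ln)) {
      val <- sub("^(AC|ID)\\s+", "", ln)
      if (is.na(id)) id <- trimws(val)
      next
    }
    if (grepl("^DE\\s", ln)) { de <- trimws(sub("^DE\\s+", "", ln)); next }
    if (grepl("^P[O0]\\s", ln)) {
      hdr <- strsplit(trimws(sub("^P[O0]\\s+", "", ln)), "\\s+")[[1]]
      if (!identical(toupper(hdr[1:4]), DNA_BASES))
        .parse_error(path, i, "matrix header must list columns A C G T")
      in_matrix <- TRUE; next
    }
    if (in_matrix && grepl("^\\d+\\s", ln)) {
      vals <- suppressWarnings(
        as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2:5]))
      if (any(is.na(vals))) .parse_error(path, i, "malformed matrix row")
      rows[[length(rows) + 1L]] <- vals
      next
    }
    if (grepl("^XX", ln) || !nzchar(trimws(ln))) { in_matrix <- FALSE; next }
  }
  flush(length(lines))
  motifs
}

.format_transfac <- function(m) {
  rows <- vapply(seq_len(motif_width(m)), function(i)
    paste0(sprintf("%02d", i), "  ",
           paste(.num(m$counts[i, ]), collapse = "  ")), character(1))
  c(paste("AC", m$id), "XX", paste("ID", m$id), "XX",
    if (!is.null(m$description)) c(paste("DE", m$description), "XX"),
    "P0  A  C  G  T", rows, "XX", "//")
}

## ---- MEME minimal ------------------------------------------------------

.read_meme <- function(lines, path) {
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (grepl("^MOTIF\\s", ln)) {
      id <- strsplit(trimws(sub("^MOTIF\\s+", "", ln)), "\\s+")[[1]][1]
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", lines[[j]])) j <- j + 1L
      if (j > length(lines))
        .parse_error(path, i, "MOTIF block without letter-probability matrix")
      hdr <- lines[[j]]
      w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
      ns <- suppressWarnings(
        as.numeric(sub(".*\\bnsites=\\s*([0-9.eE+-]+).*", "\\1", hdr)))
      if (is.na(w)) .parse_error(path, j, "missing w= in matrix header")
      if (is.na(ns)) ns <- 20
      freq <- matrix(NA_real_, w, 4L)
      for (k in seq_len(w)) {
        vals <- suppressWarnings(
          as.numeric(strsplit(trimws(lines[[j + k]]), "\\s+")[[1]]))
        if (length(vals) != 4L || any(is.na(vals)))
          .parse_error(path, j + k, "malformed probability row")
        freq[k, ] <- vals
      }
      motifs[[length(motifs) + 1L]] <-
        nucleotide_motif(id, freq * ns, nsites = ns)
      i <- j + w + 1L
    } else i <- i + 1L
  }
  motifs
}

.format_meme <- function(motifs) {
  head <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
            "Background letter frequencies",
            "A 0.25 C 0.25 G 0.25 T 0.25", "")
  body <- unlist(lapply(motifs, function(m) {
    freq <- m$counts / rowSums(m$counts)
    c(paste("MOTIF", m$id),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %s E= 0",
              motif_width(m), .num(m$nsites)),
      vapply(seq_len(nrow(freq)), function(i)
        paste(" ", paste(.num(freq[i, ]), collapse = "  ")), character(1)),
      "")
  }))
  c(head, body)
}

## ---- JASPAR PFM --------------------------------------------------------

.read_jaspar <- function(lines, path) {
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^>", lines[[i]])) {
      id <- strsplit(sub("^>\\s*", "", lines[[i]]), "\\s+")[[1]][1]
      rows <- matrix(NA_real_, 4L, 0L)
      for (k in 1:4) {
        if (i + k > length(lines)) .parse_error(path, i, "truncated PFM record")
        ln <- lines[[i + k]]
        base <- sub("^\\s*([ACGT]).*", "\\1", ln)
        if (!identical(base, DNA_BASES[k]))
          .parse_error(path, i + k,
                       paste0("expected row for base ", DNA_BASES[k]))
        nums <- gsub("[][]", " ", sub("^\\s*[ACGT]", "", ln))
        vals <- suppressWarnings(
          as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
        if (any(is.na(vals)) || length(vals) == 0L)
          .parse_error(path, i + k, "malformed PFM row")
        if (k == 1L) rows <- matrix(NA_real_, 4L, length(vals))
        if (length(vals) != ncol(rows))
          .parse_error(path, i + k, "ragged PFM rows")
        rows[k, ] <- vals
      }
      motifs[[length(motifs) + 1L]] <- nucleotide_motif(id, t(rows))
      i <- i + 5L
    } else i <- i + 1L
  }
  motifs
}

.format_jaspar <- function(m) {
  c(paste0(">", m$id),
    vapply(1:4, function(k)
      paste0(DNA_BASES[k], " [ ",
             paste(.num(m$counts[, k]), collapse = " "), " ]"),
      character(1)))
}
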