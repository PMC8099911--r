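BASES <- c("A", "C", "G", "T")

#' Read JASPAR-format PFM text
#'
#' Parses JASPAR (2016+) text: records start with a `>` header line
#' (identifier and optional name), followed by four labelled rows, e.g.
#' `A [ 3 21 0 ]`. Row labels are honoured, so files listing rows in a
#' different order are normalised to A, C, G, T.
#'
#' @param path file path (or a character vector of lines via
#'   \code{text}).
#' @param text optional character vector of lines, used instead of
#'   \code{path}.
#' @param pseudocount,background passed to [PFMModel()].
#' @return A named list of [PFMModel-class] objects (one per record).
#' @export
readJaspar <- function(path, text = NULL, pseudocount = 0.25,
                       background = rep(0.25, 4)) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR record headers ('>') found")
  ends <- c(starts[-1] - 1L, length(lines))
  models <- list()
  for (k in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    fields <- strsplit(hdr, "\\s+")[[1]]
    name <- if (length(fields) >= 2) fields[2] else fields[1]
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 4L)
      stop("record '", name, "' must have exactly 4 matrix rows, found ",
           length(body))
    rows <- lapply(body, function(ln) {
      lab <- toupper(sub("^([ACGTacgt]).*", "\\1", ln))
      if (!lab %in% BASES)
        stop("cannot parse base label in line: '", ln, "'")
      num <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(num),
                                                   "\\s+")[[1]]))
      if (anyNA(vals))
        stop("non-numeric counts in line: '", ln, "'")
      if (any(vals < 0))
        stop("negative counts in line: '", ln, "'")
      list(lab = lab, vals = vals)
    })
    w <- unique(vapply(rows, function(r) length(r$vals), 1L))
    if (length(w) != 1L)
      stop("ragged rows in record '", name, "'")
    cts <- matrix(0, 4L, w, dimnames = list(BASES, NULL))
    for (r in rows) cts[r$lab, ] <- r$vals
    models[[name]] <- PFMModel(name, cts, pseudocount = pseudocount,
                               background = background)
  }
  models
}

#' Write PFMModels as JASPAR text
#' @param models list of [PFMModel-class] (or a single model).
#' @param path output file.
#' @export
writeJaspar <- function(models, path) {
  if (is(models, "PFMModel")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    writeLines(paste0(">", m@tfName, "\t", m@tfName), con)
    for (b in BASES)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m@counts[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' @export
motifWidth <- function(pfm) ncol(pfm@counts)

#' @export
tfName <- function(pfm) pfm@tfName

#' Column probability matrix of a PFM
#'
#' \eqn{p_{ij} = (c_{ij} + pc) / (N_j + 4 pc)} with \eqn{N_j} the column
#' count total and \eqn{pc} the model pseudocount.
#' @param pfm a [PFMModel-class].
#' @return 4 x w probability matrix.
#' @export
probabilityMatrix <- function(pfm) {
  cts <- pfm@counts
  pc <- pfm@pseudocount
  sweep(cts + pc, 2L, colSums(cts) + 4 * pc, "/")
}

#' Log-odds (PWM) scoring matrix, base 2
#' @param pfm a [PFMModel-class].
#' @export
logOddsMatrix <- function(pfm) {
  log2(probabilityMatrix(pfm) / pfm@background)
}

#' Motif information content (specificity) in bits
#'
#' \eqn{IC = \sum_j (2 + \sum_i p_{ij} \log_2 p_{ij})}, with
#' \eqn{0 \log 0 = 0}. Motifs under 8 bits are conventionally excluded
#' from candidate scans.
#' @param pfm a [PFMModel-class].
#' @return total bits across columns.
#' @export
informationContent <- function(pfm) {
  p <- probabilityMatrix(pfm)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sum(2 + colSums(plogp))
}

#' Consensus sequence (argmax base per column)
#' @param pfm a [PFMModel-class].
#' @export
consensusSequence <- function(pfm) {
  paste(BASES[apply(pfm@counts, 2L, which.max)], collapse = "")
}

revCompLogOdds <- function(lo) {
  # complement rows (A<->T, C<->G) and reverse columns
  lo[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(lo))), drop = FALSE]
}

scoreWindows <- function(codes, lo) {
  w <- ncol(lo)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    sc <- sc + lo[cbind(cj, j)]   # NA codes (N bases) propagate NA
  }
  sc
}

#' Scan a sequence with a PWM at a relative-score threshold
#'
#' Scores every window on both strands with the base-2 log-odds matrix
#' and emits hits whose relative score
#' \eqn{(score - s_{min}) / (s_{max} - s_{min})} reaches
#' \code{relThreshold} (ties at the threshold included). \eqn{s_{min}}
#' and \eqn{s_{max}} are the minimum/maximum attainable matrix scores,
#' the standard convention behind a "90\% matrix score" cutoff. Windows
#' containing N are skipped. An optional per-base conservation mask
#' restricts scanning to windows whose minimum mask value reaches
#' \code{maskCutoff}.
#'
#' @param seq a single DNAString / character sequence over A,C,G,T,N.
#' @param pfm a [PFMModel-class].
#' @param relThreshold relative score threshold in (0, 1] (default 0.9).
#' @param mask optional numeric vector, one value per base (e.g.
#'   precomputed conservation scores).
#' @param maskCutoff minimum mask value (default 0.40).
#' @return data.frame with columns \code{start} (0-based), \code{width},
#'   \code{strand}, \code{score}, \code{rel_score}, sorted by
#'   (start, strand).
#' @export
scanSequence <- function(seq, pfm, relThreshold = 0.9, mask = NULL,
                         maskCutoff = 0.40) {
  stopifnot(relThreshold > 0, relThreshold <= 1)
  s <- toupper(as.character(seq))
  chars <- strsplit(s, "")[[1]]
  codes <- match(chars, BASES)            # N and others -> NA
  lo <- logOddsMatrix(pfm)
  w <- ncol(lo)
  if (length(codes) < w)
    return(emptyHits())
  smin <- sum(apply(lo, 2L, min))
  smax <- sum(apply(lo, 2L, max))
  denom <- smax - smin
  keepWindow <- NULL
  if (!is.null(mask)) {
    if (length(mask) != length(codes))
      stop("mask length must equal sequence length")
    n <- length(codes) - w + 1L
    keepWindow <- vapply(seq_len(n), function(i)
      min(mask[i:(i + w - 1L)]) >= maskCutoff, logical(1))
  }
  collect <- function(sc, strand) {
    rel <- if (is.finite(denom) && denom > 0) (sc - smin) / denom
           else ifelse(is.finite(sc), 1, -Inf)  # zero-count columns:
                                                # any attainable window
                                                # is maximal relative
                                                # to an -Inf floor
    ok <- !is.na(sc) & rel >= relThreshold
    if (!is.null(keepWindow)) ok <- ok & keepWindow
    idx <- which(ok)
    data.frame(start = idx - 1L, width = rep(w, length(idx)),
               strand = rep(strand, length(idx)),
               score = sc[idx], rel_score = rel[idx],
               stringsAsFactors = FALSE)
  }
  fwd <- collect(scoreWindows(codes, lo), "+")
  rev <- collect(scoreWindows(codes, revCompLogOdds(lo)), "-")
  out <- rbind(fwd, rev)
  out[order(out$start, out$strand), , drop = FALSE]
}

emptyHits <- function(seqId = FALSE) {
  d <- data.frame(start = integer(), width = integer(),
                  strand = character(), score = numeric(),
                  rel_score = numeric(), stringsAsFactors = FALSE)
  if (seqId) cbind(data.frame(seq_id = character()), d) else d
}

#' Scan a set of sequences
#'
#' @param seqs named \code{DNAStringSet} or named character vector.
#' @param pfm a [PFMModel-class].
#' @param relThreshold relative score threshold.
#' @param masks optional named list of per-base masks.
#' @param maskCutoff minimum mask value.
#' @return data.frame as [scanSequence()] plus a \code{seq_id} column.
#' @export
scanSequences <- function(seqs, pfm, relThreshold = 0.9, masks = NULL,
                          maskCutoff = 0.40) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  res <- lapply(seq_along(seqs), function(i) {
    h <- scanSequence(seqs[[i]], pfm, relThreshold,
                      mask = masks[[ids[i]]], maskCutoff = maskCutoff)
    if (nrow(h)) cbind(data.frame(seq_id = ids[i],
                                  stringsAsFactors = FALSE), h)
    else emptyHits(seqId = TRUE)
  })
  do.call(rbind, res)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul–Erikson shuffle: permutes a sequence while preserving its
#' exact dinucleotide counts, by sampling a random Eulerian walk on the
#' dinucleotide multigraph. Used as the default background model for
#' co-occupancy enrichment.
#'
#' @param seq single sequence (character or DNAString).
#' @return shuffled character sequence of the same length.
#' @export
dinucShuffle <- function(seq) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  n <- length(s)
  if (n <= 2L) return(paste(s, collapse = ""))
  verts <- unique(s)
  edges <- lapply(verts, function(v) s[which(s[-n] == v) + 1L])
  names(edges) <- verts
  last <- s[n]
  # pick, for each non-terminal vertex, a random final edge forming a
  # tree toward the terminal vertex, then shuffle the remaining edges
  repeat {
    lastEdge <- vapply(verts, function(v) {
      if (v == last) NA_character_
      else sample(edges[[v]], 1L)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      seen <- character()
      cur <- v
      while (!is.na(lastEdge[cur]) && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- lastEdge[cur]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  shuffled <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v == last) return(sample(e))
    drop <- match(lastEdge[v], e)
    c(sample(e[-drop]), lastEdge[v])
  })
  names(shuffled) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1L] <- s[1L]
  cur <- s[1L]
  for (i in 2L:n) {
    nxt <- shuffled[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
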