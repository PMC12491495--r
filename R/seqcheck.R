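#' Docking strand object
#'
#' A speed-optimized docking strand: a short motif concatenated
#' `n_repeats` times (optionally with a spacer), labeled with its
#' chirality class — natural right-handed DNA (`"R"`) or mirror-image
#' left-handed DNA (`"L"`). Mirror DNA hybridizes only within its own
#' chirality class, which is what makes a combined L/R library orthogonal
#' by construction.
#'
#' @param sequence 5'->3' sequence over A/C/G/T.
#' @param chirality `"L"` or `"R"`.
#' @param repeat_unit Motif the sequence is built from.
#' @param n_repeats Number of tandem repeats.
#' @param name Strand name (e.g. `"R1"`, `"L4"`).
#' @param spacer Spacer between repeats (may be `""`).
#' @return A `docking_strand` list.
#' @export
docking_strand <- function(sequence, chirality, repeat_unit = sequence,
                           n_repeats = 1L, name = NA_character_,
                           spacer = "") {
  chirality <- match.arg(chirality, c("L", "R"))
  check_alphabet(sequence)
  out <- list(sequence = toupper(sequence), chirality = chirality,
              repeat_unit = toupper(repeat_unit),
              n_repeats = as.integer(n_repeats),
              name = name, spacer = toupper(spacer))
  class(out) <- "docking_strand"
  out
}

#' @export
print.docking_strand <- function(x, ...) {
  cat(sprintf("<docking_strand> %s (%s-DNA): %s  [%dx %s]\n",
              ifelse(is.na(x$name), "?", x$name), x$chirality, x$sequence,
              x$n_repeats, x$repeat_unit))
  invisible(x)
}

check_alphabet <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L) {
    stop("sequence must be a single string", call. = FALSE)
  }
  if (nchar(seq) > 0 && grepl("[^ACGTacgt]", seq)) {
    stop("invalid characters in sequence (alphabet is A/C/G/T): ", seq,
         call. = FALSE)
  }
  invisible(seq)
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}

#' Build a concatenated docking strand
#'
#' @param motif Repeat motif (non-empty, A/C/G/T).
#' @param n_repeats Number of tandem repeats (>= 1).
#' @param spacer Optional spacer inserted between repeats.
#' @param chirality,name Passed to [docking_strand()].
#' @return A `docking_strand` of length
#'   `n * nchar(motif) + (n - 1) * nchar(spacer)`.
#' @export
build_concatemer <- function(motif, n_repeats, spacer = "",
                             chirality = "R", name = NA_character_) {
  check_alphabet(motif)
  check_alphabet(spacer)
  if (nchar(motif) == 0) stop("build_concatemer: empty motif",
                              call. = FALSE)
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("build_concatemer: `n_repeats` must be >= 1",
                           call. = FALSE)
  seq <- paste(rep(toupper(motif), n_repeats),
               collapse = toupper(spacer))
  docking_strand(seq, chirality, repeat_unit = motif,
                 n_repeats = n_repeats, name = name, spacer = spacer)
}

#' Decompose a concatemer into its repeat unit
#'
#' Finds the shortest motif whose tandem repetition (no spacer)
#' reconstructs the sequence.
#'
#' @param strand A `docking_strand` or a plain sequence string.
#' @return List with `motif` and `n_repeats`.
#' @export
decompose_concatemer <- function(strand) {
  seq <- if (inherits(strand, "docking_strand")) strand$sequence
         else toupper(strand)
  check_alphabet(seq)
  n <- nchar(seq)
  for (p in seq_len(n)) {
    if (n %% p != 0) next
    motif <- substr(seq, 1, p)
    if (paste(rep(motif, n %/% p), collapse = "") == seq) {
      return(list(motif = motif, n_repeats = n %/% p))
    }
  }
  list(motif = seq, n_repeats = 1L)
}

#' Longest possible hairpin stem of a strand
#'
#' Length of the longest pair of reverse-complementary substrings of the
#' strand separated by at least `min_loop` nucleotides — the longest stem
#' a hairpin could form. Computed by dynamic programming over base-pair
#' runs (equivalent to brute force over substring pairs).
#'
#' @param strand A `docking_strand` or sequence string.
#' @param min_loop Minimum loop length, nt.
#' @return Maximum stem length, nt (0 when nothing can pair).
#' @export
max_selfcomp_stem <- function(strand, min_loop = 3L) {
  seq <- if (inherits(strand, "docking_strand")) strand$sequence
         else toupper(strand)
  check_alphabet(seq)
  n <- nchar(seq)
  if (n < 2 + min_loop) return(0L)
  s <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs <- outer(s, s, function(a, b) comp[a] == b)
  best <- 0L
  # run[i, j]: number of consecutive complementary pairs
  # (i, j), (i+1, j-1), ... — the stem depth available from outer pair
  # (i, j). A stem of depth L there leaves a loop of j - i + 1 - 2L nt,
  # so min_loop caps L at floor((j - i + 1 - min_loop) / 2).
  run <- matrix(0L, n, n)
  for (i in (n - 1):1) {
    for (j in (i + 1):n) {
      if (!pairs[i, j]) next
      r <- 1L + run[i + 1, j - 1]
      run[i, j] <- r
      l_ok <- min(r, (j - i + 1 - min_loop) %/% 2)
      if (l_ok > best) best <- l_ok
    }
  }
  as.integer(best)
}

#' Is a strand hairpin-free?
#'
#' @param strand A `docking_strand` or sequence string.
#' @param max_stem Largest tolerated stem length; stems of this length or
#'   longer fail (default 3).
#' @param min_loop Minimum loop length, nt.
#' @return TRUE when the longest possible stem is shorter than `max_stem`.
#' @export
is_hairpin_free <- function(strand, max_stem = 3L, min_loop = 3L) {
  max_selfcomp_stem(strand, min_loop) < max_stem
}

#' Longest complementary run between a docking strand and an imager
#'
#' Zero by definition when the chiralities differ (mirror-image DNA does
#' not hybridize with natural DNA); otherwise the length of the longest
#' contiguous reverse-complementary match between the two sequences.
#'
#' @param a A `docking_strand`.
#' @param b Imager: a `docking_strand` or a list/character with `sequence`
#'   and `chirality`.
#' @return Longest complementary run, nt.
#' @export
cross_hyb_score <- function(a, b) {
  stopifnot(inherits(a, "docking_strand"))
  if (is.character(b)) stop("cross_hyb_score: `b` needs a chirality; pass ",
                            "a docking_strand or list(sequence, chirality)",
                            call. = FALSE)
  if (a$chirality != b$chirality) return(0L)
  sa <- a$sequence
  sb <- revcomp(b$sequence)
  longest_common_substring(sa, sb)
}

longest_common_substring <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  na <- length(va); nb <- length(vb)
  if (na == 0 || nb == 0) return(0L)
  prev <- integer(nb)
  best <- 0L
  for (i in seq_len(na)) {
    cur <- integer(nb)
    match_i <- va[i] == vb
    cur[match_i] <- 1L
    if (nb > 1) {
      idx <- which(match_i)[which(match_i) > 1L]
      cur[idx] <- prev[idx - 1L] + 1L
    }
    m <- max(cur)
    if (m > best) best <- m
    prev <- cur
  }
  as.integer(best)
}

#' Pairwise cross-hybridization matrix of a library
#'
#' Treats each strand's perfect imager (reverse complement, same
#' chirality) as the probe and scores it against every docking strand.
#' For any chirality-mixed library the matrix is block-diagonal: the
#' cross-chirality blocks are exactly zero.
#'
#' @param strands List of `docking_strand`s.
#' @return Integer matrix of longest complementary runs; entry (i, j) is
#'   the score of strand i against the imager of strand j.
#' @export
cross_hyb_matrix <- function(strands) {
  n <- length(strands)
  nm <- vapply(strands, function(s) {
    if (is.na(s$name)) "?" else s$name
  }, character(1))
  out <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (j in seq_len(n)) {
    imager <- list(sequence = revcomp(strands[[j]]$sequence),
                   chirality = strands[[j]]$chirality)
    for (i in seq_len(n)) {
      out[i, j] <- cross_hyb_score(strands[[i]], imager)
    }
  }
  out
}

#' Placeholder speed-optimized docking library
#'
#' Twelve concatemer strands named R1-R6 and L1-L6 built from placeholder
#' repeat motifs (the published supplementary sequences are not bundled);
#' useful for exercising the library checks. User libraries can be
#' supplied anywhere a list of [docking_strand()]s is accepted.
#'
#' @param n_repeats Tandem repeats per strand.
#' @return Named list of 12 `docking_strand`s.
#' @export
speed_library <- function(n_repeats = 5L) {
  motifs <- c("TCCTCCC", "ACCACCA", "TCCTCCA", "ACCTCCT", "TCCACCA",
              "ACCACCT")
  out <- list()
  for (ch in c("R", "L")) {
    for (k in seq_along(motifs)) {
      nm <- paste0(ch, k)
      out[[nm]] <- build_concatemer(motifs[k], n_repeats, chirality = ch,
                                    name = nm)
    }
  }
  out
}
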