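#' Characteristic-domain specification
#'
#' A ribozyme function is conferred by a stem-loop sequence motif: `stem_len`
#' stem residues, a 4-base function-specific loop, and `stem_len` residues
#' complementary (Watson-Crick or G-U wobble) to the first arm in reverse
#' order, i.e. the motif `X_s..X_1 L L L L Y_1..Y_s` with `X_i` pairing `Y_i`.
#' A strand whose length is at least twice the domain length is assumed to be
#' misfolded by the redundant residues and carries no function.
#'
#' @param stem_len residues per stem arm (3 for the small system, 8 for the
#'   larger-scale system).
#' @param loops named character vector of 4-base loops, one per function.
#' @return An object of class `rw_domain` with fields `stem_len`, `loops`,
#'   `domain_len`.
#' @export
#' @examples
#' domain_spec()          # 10-nt domain
#' domain_spec(stem_len = 8)  # 20-nt domain
domain_spec <- function(stem_len = 3,
                        loops = c(REP = "AGUC", NSR = "ACUG",
                                  ASR = "AUCG", CONTROL = "UCAG")) {
  stopifnot(is.numeric(stem_len), length(stem_len) == 1, stem_len >= 3)
  stem_len <- as.integer(stem_len)
  loops <- toupper(loops)
  if (length(loops) != 4 || !setequal(names(loops), RNA_CLASSES)) {
    abort("loops must be named REP, NSR, ASR, CONTROL")
  }
  if (any(nchar(loops) != 4) || any(duplicated(loops))) {
    abort("loops must be four pairwise-distinct 4-base sequences")
  }
  if (!all(strsplit(paste(loops, collapse = ""), "")[[1]] %in%
           c("A", "U", "C", "G"))) {
    abort("loops must use the RNA alphabet AUCG")
  }
  dl <- 2L * stem_len + 4L
  if (dl < 10) abort("domain length must be >= 10")
  structure(list(stem_len = stem_len, loops = loops[RNA_CLASSES],
                 domain_len = dl),
            class = c("rw_domain", "list"))
}

#' @export
print.rw_domain <- function(x, ...) {
  cat("<rw_domain> stem", x$stem_len, "nt, domain", x$domain_len, "nt; loops:",
      paste(names(x$loops), x$loops, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Can two bases pair?
#'
#' Watson-Crick pairs (A-U, G-C) always pair; the G-U wobble pair counts only
#' when `allow_wobble` is set (wobble is accepted in the stem of the
#' characteristic domain, but template-directed copying uses strict
#' Watson-Crick complementarity).
#'
#' @param x,y single bases in `A`, `U`, `C`, `G` (vectorised).
#' @param allow_wobble accept the G-U pair.
#' @return Logical.
#' @export
#' @examples
#' bases_pair("A", "U")          # TRUE
#' bases_pair("G", "U")          # FALSE
#' bases_pair("G", "U", TRUE)    # TRUE
bases_pair <- function(x, y, allow_wobble = FALSE) {
  ok <- c("A", "U", "C", "G")
  if (!all(x %in% ok) || !all(y %in% ok)) abort("invalid base (use A/U/C/G)")
  wc <- (x == "A" & y == "U") | (x == "U" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  if (allow_wobble) {
    wc | (x == "G" & y == "U") | (x == "U" & y == "G")
  } else {
    wc
  }
}

#' Watson-Crick complement of an RNA sequence
#'
#' @param seq character string over AUCG.
#' @param reverse read the complement antiparallel (reverse complement),
#'   which is the orientation of a template-directed replication product.
#' @return Character string.
#' @export
complement_seq <- function(seq, reverse = TRUE) {
  map <- c(A = "U", U = "A", C = "G", G = "C")
  ch <- strsplit(toupper(seq), "")[[1]]
  if (!all(ch %in% names(map))) abort("invalid base (use A/U/C/G)")
  out <- unname(map[ch])
  if (reverse) out <- rev(out)
  paste(out, collapse = "")
}

# integer encoding A=0, U=1, C=2, G=3 shared with the C++ engine
seq_to_int <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  code <- match(ch, c("A", "U", "C", "G")) - 1L
  if (anyNA(code)) abort("invalid base (use A/U/C/G)")
  code
}

int_to_seq <- function(code) {
  paste(c("A", "U", "C", "G")[code + 1L], collapse = "")
}

#' Classify an RNA strand by its functional domains
#'
#' Scans every window of the domain length for a stem-loop hit: the loop must
#' exactly match one of the function-specific loops and each stem position
#' must pair (Watson-Crick or G-U wobble).  A strand at least twice the
#' domain length carries no function regardless of its windows.
#'
#' @param seq character string over AUCG (length >= 2).
#' @param spec an [domain_spec()] object.
#' @return Character vector of matched classes (subset of
#'   `REP, NSR, ASR, CONTROL`), possibly empty.
#' @export
#' @examples
#' classify_rna(ribozyme_sequence("REP"), domain_spec())
classify_rna <- function(seq, spec = domain_spec()) {
  stopifnot(nchar(seq) >= 1)
  mask <- classify_seq_cpp(seq_to_int(seq), spec$stem_len,
                           lapply(spec$loops, seq_to_int))
  RNA_CLASSES[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0]
}

#' Minimal sequence realizing a ribozyme domain
#'
#' The inoculated copies of each species are the minimal domain-length
#' sequence for that function: the lexicographically first valid stem (an
#' all-A first arm paired by an all-U second arm) around the function's loop.
#' Its length equals the domain length, so the twice-length rule is satisfied.
#'
#' @param class one of `REP`, `NSR`, `ASR`, `CONTROL`.
#' @param spec an [domain_spec()] object.
#' @return Character string of length `spec$domain_len`.
#' @export
ribozyme_sequence <- function(class, spec = domain_spec()) {
  class <- match.arg(class, RNA_CLASSES)
  paste0(strrep("A", spec$stem_len), spec$loops[[class]],
         strrep("U", spec$stem_len))
}
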