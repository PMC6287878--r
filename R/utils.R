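#' @importFrom data.table data.table as.data.table setorder := fread fwrite
#'   setattr rbindlist setnames .N .SD
#' @importFrom stats lm coef vcov quantile rbinom runif kruskal.test
#'   chisq.test p.adjust pchisq pnorm var sd setNames
#' @importFrom utils head tail
#' @importFrom methods is
NULL

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

#' Reverse complement of a character vector of DNA strings
#' @param x character vector over A/C/G/T
#' @return character vector
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

is_pyrimidine <- function(b) b == "C" | b == "T"
is_purine <- function(b) b == "A" | b == "G"

#' Dipyrimidine-context test on base vectors
#'
#' A position is in dipyrimidine context when its reference base forms a
#' pyrimidine-pyrimidine pair with an adjacent base on either strand: a C/T
#' with a C/T neighbour on the reference strand, or an A/G with an A/G
#' neighbour (a pyrimidine pair on the reverse strand).
#'
#' @param prev,ref,nxt single-character base vectors (5' flank, the base,
#'   3' flank on the reference strand)
#' @return logical vector
#' @export
is_dipyr_context <- function(prev, ref, nxt) {
  (is_pyrimidine(ref) & (is_pyrimidine(prev) | is_pyrimidine(nxt))) |
    (is_purine(ref) & (is_purine(prev) | is_purine(nxt)))
}

#' Does a trinucleotide contain a dipyrimidine on either strand?
#'
#' TRUE when any adjacent pair within the 3-mer is YY or RR on the reference
#' strand (RR reads as a pyrimidine pair on the reverse strand).
#' @param trinuc character vector of 3-mers
#' @return logical vector
#' @export
trinuc_has_dipyr <- function(trinuc) {
  b1 <- substr(trinuc, 1L, 1L)
  b2 <- substr(trinuc, 2L, 2L)
  b3 <- substr(trinuc, 3L, 3L)
  pair_yy_rr <- function(a, b) {
    (is_pyrimidine(a) & is_pyrimidine(b)) | (is_purine(a) & is_purine(b))
  }
  pair_yy_rr(b1, b2) | pair_yy_rr(b2, b3)
}

# all 64 trinucleotides in fixed lexicographic order
all_trinucs <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

# deterministic short hash (FNV-1a over the deparsed object), used to stamp
# output files so reruns are byte-identical for identical configs; arithmetic
# kept in doubles below 2^53 (xor emulated per-bit on the low 32 bits)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor of h's low byte with b, leaving the high bytes of h intact
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# seeded evaluation that restores the RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

msg <- function(...) message("[nucsig] ", sprintf(...))
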