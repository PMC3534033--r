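# Small internal helpers shared across modules.

#' @importFrom Biostrings DNAString AAString reverseComplement
NULL

# Normalize a nucleotide string: uppercase, RNA -> DNA alphabet (U -> T).
norm_nt <- function(x) {
  x <- toupper(as.character(x))
  chartr("U", "T", x)
}

# Reverse-complement a plain character nucleotide string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(norm_nt(x))))
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Fraction of U/T in a nucleotide string.
u_fraction <- function(x) {
  v <- chars(norm_nt(x))
  if (length(v) == 0L) return(NA_real_)
  mean(v == "T")
}

# A+T fraction (percent) of a nucleotide string.
at_percent <- function(x) {
  v <- chars(norm_nt(x))
  100 * mean(v %in% c("A", "T"))
}

# Point-mutate a nucleotide string at a given per-site substitution rate.
# Substitutions always change the base. Uses the current RNG stream.
mutate_seq <- function(x, rate) {
  stopifnot(rate >= 0, rate <= 1)
  v <- chars(norm_nt(x))
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  paste(v, collapse = "")
}

# Write a data.frame as TSV (no quoting, no row names).
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, fill = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
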