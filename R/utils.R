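# Internal helpers shared across modules.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

MOD_KINDS <- c("deamidation", "carbamidomethyl", "oxidation")

# Residues a given modification kind may sit on. Deamidation annotations are
# accepted on D/E as well as N/Q because simulated (and many real) de novo
# sequences report the converted residue while keeping the annotation.
MOD_TARGETS <- list(
  deamidation     = c("N", "Q", "D", "E"),
  carbamidomethyl = "C",
  oxidation       = "M"
)

is_standard_seq <- function(x) {
  grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), x)
}

#' @noRd
stop2 <- function(...) stop(..., call. = FALSE)

# Deterministic 31-bit stream seed derived from a base seed and a string key,
# so every sample / stage gets an independent reproducible RNG stream.
derive_seed <- function(seed, key) {
  h <- 0
  for (v in utf8ToInt(as.character(key))) h <- (h * 31 + v) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435) %% 2147483647)
}

# Parse "pos:kind;pos:kind" mod strings into a data.frame(pos, kind).
parse_mods <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(pos = integer(), kind = character()))
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  pieces <- strsplit(parts, ":", fixed = TRUE)
  bad <- lengths(pieces) != 2
  if (any(bad)) stop2("malformed mods field: '", x, "'")
  pos <- suppressWarnings(as.integer(vapply(pieces, `[`, "", 1L)))
  kind <- vapply(pieces, `[`, "", 2L)
  if (anyNA(pos)) stop2("malformed mods field: '", x, "'")
  data.frame(pos = pos, kind = kind)
}

format_mods <- function(pos, kind) {
  if (length(pos) == 0) return("")
  paste(sprintf("%d:%s", pos, kind), collapse = ";")
}
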