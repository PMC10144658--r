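#' @keywords internal
"_PACKAGE"

# Deterministic 32-bit string hash (FNV-1a style), used to derive
# stage-local seeds from the single run seed so that every stochastic
# stage has its own reproducible RNG stream.
hash_string32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

#' Derive a stage-local seed from a master seed
#'
#' Combines an integer master seed with a stage label (and optional
#' iteration index) into a deterministic seed below 2^31, so that each
#' stochastic stage of the pipeline draws from its own reproducible
#' stream regardless of what ran before it.
#'
#' @param seed integer master seed.
#' @param stage character label of the stage.
#' @param index optional integer (e.g. iteration number).
#' @return an integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  hash_string32(paste(seed, stage, index, sep = "/"))
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# TSV writers: tab-separated, no quoting, floats at 6 significant digits
# (the package's canonical output dialect).
format_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15 & !is.double(x),
                as.character(x), formatC(x, digits = 6, format = "g")))
}

write_tsv_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

msg <- function(...) message("[coopbalance] ", sprintf(...))
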