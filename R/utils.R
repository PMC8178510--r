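#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. This is the single FDR routine
#' used by every screening stage (cis-eQTL calling, weak-instrument screen,
#' differential expression, survival), so all q-values in the pipeline are
#' mutually consistent.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return Adjusted q-values, monotone non-decreasing in `p`, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  pv <- p[!is.na(p)]
  if (length(pv) > 0L && (min(pv) < 0 || max(pv) > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Derive a per-stage RNG seed from one root seed. Documented scheme: the
# stage name is folded into the root seed through a small multiplicative
# hash, keeping the result a valid 32-bit R integer. Each generator stage
# calls stream_seed(seed, "<stage>") so stages are independently
# reproducible regardless of how many draws other stages consume.
stream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded from (seed, stage);
# restores the caller's RNG state afterwards.
with_stream <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stage))
  expr
}

# Write a data.frame as TSV with a fixed, locale-independent layout.
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA",
                     scipen = 50)
  invisible(path)
}

read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                  data.table = FALSE, ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
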