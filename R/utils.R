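# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs `expr` with the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  as.list((as.double(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647)
}

stop_femnet <- function(...) stop(..., call. = FALSE)

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_femnet(name, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_femnet(name, " must have row and column names")
  invisible(x)
}

check_phenotype <- function(phen) {
  need <- c("sample_id", "group")
  if (!is.data.frame(phen) || !all(need %in% names(phen)))
    stop_femnet("phenotype table needs columns sample_id and group")
  if (!all(phen$group %in% c("normal", "tumour")))
    stop_femnet("phenotype group must be 'normal' or 'tumour'")
  if (anyDuplicated(phen$sample_id))
    stop_femnet("duplicated sample_id in phenotype table")
  if (!"subtype" %in% names(phen)) phen$subtype <- "none"
  if (!all(phen$subtype %in% c("lumA", "lumB", "none")))
    stop_femnet("phenotype subtype must be 'lumA', 'lumB' or 'none'")
  phen
}

check_gene_stats <- function(stats, name = "stats") {
  if (!is.data.frame(stats) || !all(c("gene", "t", "p") %in% names(stats)))
    stop_femnet(name, " must be a data.frame with columns gene, t, p")
  if (anyDuplicated(stats$gene))
    stop_femnet(name, ": one record per gene required")
  stats
}
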