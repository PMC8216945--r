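#' Mutation-rate parameters for Y-chromosome dating
#'
#' Bundles the inputs of the Y mutation-rate derivation: the autosomal
#' per-generation rate, the male-to-female mutation rate ratio `alpha`
#' (male germlines undergo more divisions, so Y-transmitted lineages mutate
#' faster than the genome average), the generation time, and — for
#' concatenated-SNP input — the monitored sequence length and the number of
#' SNP columns it was reduced to.
#'
#' @param mu_auto_per_gen autosomal mutation rate, substitutions/bp/
#'   generation (default 1.3e-8).
#' @param alpha male-to-female mutation rate ratio (default 2.0).
#' @param gen_time generation time in years (default 2).
#' @param seq_len monitored sequence length L in bp (optional, for
#'   rescaling).
#' @param n_snp number of concatenated SNP columns (optional).
#' @return an object of class `rate_spec`.
#' @export
rate_spec <- function(mu_auto_per_gen = 1.3e-8, alpha = 2.0, gen_time = 2,
                      seq_len = NULL, n_snp = NULL) {
  stopifnot(mu_auto_per_gen > 0, alpha >= 0, gen_time > 0,
            is.null(seq_len) || seq_len > 0, is.null(n_snp) || n_snp > 0)
  structure(list(mu_auto_per_gen = mu_auto_per_gen, alpha = alpha,
                 gen_time = gen_time, seq_len = seq_len, n_snp = n_snp),
            class = "rate_spec")
}

#' Y-chromosome substitution rate per bp per year
#'
#' The Y is transmitted through male germlines only, so its per-generation
#' rate is the male-lineage rate `mu_auto * 2 * alpha / (1 + alpha)` (the
#' autosomal rate is the male/female average `(mu_m + mu_f) / 2` with
#' `mu_m = alpha * mu_f`). Dividing by the generation time converts to a
#' per-year rate. With the defaults (mu = 1.3e-8, alpha = 2, g = 2 years)
#' this gives 8.67e-9 substitutions/bp/year.
#'
#' @param spec a [rate_spec()] (or its fields passed individually).
#' @return substitutions per bp per year.
#' @export
y_rate_per_year <- function(spec = rate_spec()) {
  stopifnot(inherits(spec, "rate_spec"))
  if (spec$gen_time == 0) stop("gen_time must be positive", call. = FALSE)
  mu_y_gen <- spec$mu_auto_per_gen * 2 * spec$alpha / (1 + spec$alpha)
  mu_y_gen / spec$gen_time
}

#' Rescale a sequence rate for a concatenated-SNP alignment
#'
#' Each retained SNP column of a concatenated alignment stands in for
#' `L / n_snp` monitored bases, so the per-column rate is the per-bp rate
#' multiplied by that factor. Feeding this rescaled rate to a skyline or
#' clock model on the concatenated alignment recovers the time scale of the
#' full sequence.
#'
#' @param rate_seq per-bp per-year substitution rate of the full sequence.
#' @param seq_len monitored sequence length L in bp.
#' @param n_snp number of concatenated SNP columns.
#' @return per-SNP-column rate per year.
#' @export
rescale_rate_for_concat <- function(rate_seq, seq_len, n_snp) {
  stopifnot(rate_seq > 0, seq_len > 0, n_snp > 0)
  rate_seq * seq_len / n_snp
}

#' Key-value report of derived rates
#'
#' @param spec a [rate_spec()] with `seq_len` and `n_snp` set when the
#'   concatenated rate is wanted.
#' @return named numeric vector: `y_rate_per_gen`, `y_rate_per_year`, and
#'   `concat_rate_per_year` when computable.
#' @export
rate_report <- function(spec = rate_spec()) {
  per_year <- y_rate_per_year(spec)
  out <- c(y_rate_per_gen = per_year * spec$gen_time,
           y_rate_per_year = per_year)
  if (!is.null(spec$seq_len) && !is.null(spec$n_snp)) {
    out <- c(out, concat_rate_per_year =
               rescale_rate_for_concat(per_year, spec$seq_len, spec$n_snp))
  }
  out
}
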