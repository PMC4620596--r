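#' Reference state for catalytic-efficiency calibration
#'
#' Bundles a reference flux distribution (e.g. from a conventional FBA
#' solution at a known growth condition), the amounts of the catalyzing
#' compounds accumulated over the reference duration, and the map from
#' catalysts to the reactions they catalyze.
#'
#' @param v_ref named nonnegative flux vector (amount per second) over the
#'   catalyzed reactions.
#' @param M_ref named positive amounts of the catalyzing compounds.
#' @param catalysis_map named list: catalyst id -> character vector of
#'   reaction ids it catalyzes.
#' @param T_ref_hours duration over which `M_ref` is synthesized
#'   (default 12, a light phase).
#' @return object of class `cfba_reference`.
#' @export
reference_state <- function(v_ref, M_ref, catalysis_map, T_ref_hours = 12) {
  stopifnot(is.numeric(v_ref), !is.null(names(v_ref)),
            is.numeric(M_ref), !is.null(names(M_ref)),
            is.list(catalysis_map), !is.null(names(catalysis_map)))
  for (cat_id in names(catalysis_map)) {
    rxns <- catalysis_map[[cat_id]]
    if (length(rxns) < 1) stop("empty reaction set for catalyst ", cat_id)
    if (!all(rxns %in% names(v_ref))) {
      stop("v_ref missing catalyzed reaction(s) of ", cat_id)
    }
    if (!(cat_id %in% names(M_ref))) {
      stop("M_ref missing catalyst ", cat_id)
    }
    if (M_ref[[cat_id]] <= 0) {
      stop("non-positive reference amount for catalyst ", cat_id)
    }
    if (any(v_ref[rxns] < 0)) {
      stop("negative reference flux for a catalyzed reaction of ", cat_id)
    }
  }
  structure(list(v_ref = v_ref, M_ref = M_ref,
                 catalysis_map = catalysis_map,
                 T_ref_hours = T_ref_hours),
            class = "cfba_reference")
}

#' Estimate catalytic efficiencies by self-consistency
#'
#' Under the self-consistency assumption the reference amount of each
#' catalyst is exactly sufficient to carry its own reference flux
#' distribution. For a catalyst `j` with reaction set `R_j`, the amount is
#' split equally across its `|R_j|` reactions and
#' `kcat[i,j] = |R_j| * v_ref[i] / M_ref[j]`, which makes the capacity row
#' `sum_i v_ref[i] / kcat[i,j] = M_ref[j]` hold with equality. Catalysts
#' listed in `common_kcat` (typically the ribosome over all
#' enzyme-synthesis reactions) instead share a single efficiency fitted so
#' the *summed* row is tight: `kcat[j] = sum_i v_ref[i] / M_ref[j]`.
#'
#' @param ref a [reference_state()].
#' @param common_kcat character vector of catalyst ids that share one
#'   common kcat across their reaction set.
#' @return a `cfba_kcat_table`: data.frame with columns `reaction`,
#'   `catalyst`, `kcat` (per second).
#' @export
estimate_kcats <- function(ref, common_kcat = character(0)) {
  stopifnot(inherits(ref, "cfba_reference"))
  rows <- list()
  for (cat_id in names(ref$catalysis_map)) {
    rxns <- ref$catalysis_map[[cat_id]]
    M <- ref$M_ref[[cat_id]]
    v <- ref$v_ref[rxns]
    if (cat_id %in% common_kcat) {
      tot <- sum(v)
      if (tot <= 0) {
        stop("zero total reference flux for common-kcat catalyst ", cat_id)
      }
      k <- rep(tot / M, length(rxns))
    } else {
      if (any(v <= 0)) {
        stop("zero reference flux for a catalyzed reaction of ", cat_id,
             "; cannot estimate a finite kcat")
      }
      k <- length(rxns) * v / M
    }
    rows[[cat_id]] <- data.frame(reaction = rxns, catalyst = cat_id,
                                 kcat = as.numeric(k),
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("cfba_kcat_table", class(out))
  out
}

#' Check the self-consistency of a kcat table
#'
#' Recomputes each catalyst's capacity row at the reference state and
#' flags rows whose relative slack exceeds `rtol`.
#'
#' @param kcats a `cfba_kcat_table`.
#' @param ref the [reference_state()] used for estimation.
#' @param rtol relative slack tolerance.
#' @return data.frame with columns `catalyst`, `lhs`
#'   (`sum v_ref / kcat`), `M_ref`, `rel_slack`, `tight` (logical).
#' @export
check_self_consistency <- function(kcats, ref, rtol = 1e-9) {
  cats <- names(ref$catalysis_map)
  out <- data.frame(catalyst = cats, lhs = NA_real_, M_ref = NA_real_,
                    rel_slack = NA_real_, tight = NA,
                    stringsAsFactors = FALSE)
  for (r in seq_along(cats)) {
    rxns <- ref$catalysis_map[[cats[r]]]
    sub <- kcats[kcats$catalyst == cats[r], ]
    kv <- stats::setNames(sub$kcat, sub$reaction)
    if (!all(rxns %in% names(kv))) {
      stop("kcat table does not cover catalyst ", cats[r])
    }
    lhs <- sum(ref$v_ref[rxns] / kv[rxns])
    M <- ref$M_ref[[cats[r]]]
    out$lhs[r] <- lhs
    out$M_ref[r] <- M
    out$rel_slack[r] <- abs(lhs - M) / M
    out$tight[r] <- out$rel_slack[r] <= rtol
  }
  out
}

#' Install estimated kcats into a model's capacity constraints
#'
#' Replaces `inverse_kcat` entries with `1 / kcat` for every
#' (reaction, catalyst) pair present in the table.
#'
#' @param model a [cfba_model()].
#' @param kcats a `cfba_kcat_table`.
#' @return the modified model.
#' @export
set_kcats <- function(model, kcats) {
  # kcat tables are per second; models whose capacity coefficients are
  # expressed against per-hour fluxes store (1/kcat)/3600
  conv <- if (identical(model$flux_time_unit, "hour")) 3600 else 1
  for (i in seq_along(model$capacity_constraints)) {
    cc <- model$capacity_constraints[[i]]
    sub <- kcats[kcats$catalyst == cc$catalyst, ]
    if (!nrow(sub)) next
    m <- match(cc$terms$reaction, sub$reaction)
    hit <- !is.na(m)
    cc$terms$inverse_kcat[hit] <- 1 / (sub$kcat[m[hit]] * conv)
    model$capacity_constraints[[i]] <- cc
  }
  model
}

#' Read/write kcat tables as TSV
#'
#' Columns: `reaction_id`, `catalyst_id`, `kcat_per_s`.
#'
#' @param kcats a `cfba_kcat_table`.
#' @param path file path.
#' @return `read_kcat_tsv` returns a `cfba_kcat_table`;
#'   `write_kcat_tsv` returns `path` invisibly.
#' @export
write_kcat_tsv <- function(kcats, path) {
  out <- data.frame(reaction_id = kcats$reaction,
                    catalyst_id = kcats$catalyst,
                    kcat_per_s = kcats$kcat)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_kcat_tsv
#' @export
read_kcat_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "catalyst_id", "kcat_per_s") %in% names(d)))
  out <- data.frame(reaction = d$reaction_id, catalyst = d$catalyst_id,
                    kcat = d$kcat_per_s, stringsAsFactors = FALSE)
  class(out) <- c("cfba_kcat_table", class(out))
  out
}
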