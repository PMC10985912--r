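#' Frequently recovered associations across the filter grid
#'
#' An association (unordered ASV-id pair) is frequent in a condition when it
#' appears in at least `min_networks` of that condition's networks across
#' the grid; the default 6 encodes "more than 5 networks" of a 25-network
#' grid. Records carry both conditions' occurrence counts and per-condition
#' sign tallies; the consensus sign is the simple majority over all
#' networks containing the edge, `"mixed"` on a tie.
#'
#' @param networks list with elements `snow_free` and `snow_covered`, each
#'   a list of `association_network`s (one per filter pair).
#' @param min_networks minimum per-condition network count (default 6).
#' @return `data.frame` of class `association_records`: columns `a`, `b`,
#'   `type`, `n_snow_free`, `n_snow_covered`, `frequent_snow_free`,
#'   `frequent_snow_covered`, per-condition positive counts, `n_positive`,
#'   `n_negative`, `fraction_positive`, `consensus_sign`. The grid sizes
#'   are stored in attribute `n_networks`.
#' @export
frequent_associations <- function(networks, min_networks = 6L) {
  stopifnot(min_networks >= 1L,
            all(c("snow_free", "snow_covered") %in% names(networks)))
  pool <- list()
  kingdom_of <- character(0)
  for (cond in CONDITIONS) {
    for (net in networks[[cond]]) {
      kingdom_of[net$nodes$id] <- net$nodes$kingdom
      e <- net$edges
      if (!nrow(e)) next
      pool[[length(pool) + 1L]] <- data.frame(
        key = edge_key(e$a, e$b), type = e$type, sign = e$sign,
        condition = cond, stringsAsFactors = FALSE)
    }
  }
  if (!length(pool)) {
    rec <- data.frame(a = character(0), b = character(0),
                      kingdom_a = character(0), kingdom_b = character(0),
                      type = character(0),
                      n_snow_free = integer(0), n_snow_covered = integer(0),
                      frequent_snow_free = logical(0),
                      frequent_snow_covered = logical(0),
                      n_pos_snow_free = integer(0),
                      n_pos_snow_covered = integer(0),
                      n_positive = integer(0), n_negative = integer(0),
                      fraction_positive = numeric(0),
                      consensus_sign = character(0), stringsAsFactors = FALSE)
  } else {
    all_e <- do.call(rbind, pool)
    n_sf <- table(all_e$key[all_e$condition == "snow_free"])
    n_sc <- table(all_e$key[all_e$condition == "snow_covered"])
    pos_sf <- table(all_e$key[all_e$condition == "snow_free" &
                                all_e$sign == "+"])
    pos_sc <- table(all_e$key[all_e$condition == "snow_covered" &
                                all_e$sign == "+"])
    keys <- sort(unique(all_e$key))
    cnt <- function(tab, k) {
      v <- as.integer(tab[k]); v[is.na(v)] <- 0L; v
    }
    parts <- strsplit(keys, "|", fixed = TRUE)
    nsf <- cnt(n_sf, keys); nsc <- cnt(n_sc, keys)
    npos <- cnt(pos_sf, keys) + cnt(pos_sc, keys)
    ntot <- nsf + nsc
    a_id <- vapply(parts, `[`, "", 1L)
    b_id <- vapply(parts, `[`, "", 2L)
    rec <- data.frame(
      a = a_id, b = b_id,
      kingdom_a = unname(kingdom_of[a_id]),
      kingdom_b = unname(kingdom_of[b_id]),
      type = all_e$type[match(keys, all_e$key)],
      n_snow_free = nsf, n_snow_covered = nsc,
      frequent_snow_free = nsf >= min_networks,
      frequent_snow_covered = nsc >= min_networks,
      n_pos_snow_free = cnt(pos_sf, keys),
      n_pos_snow_covered = cnt(pos_sc, keys),
      n_positive = npos, n_negative = ntot - npos,
      fraction_positive = npos / ntot,
      consensus_sign = ifelse(npos * 2L > ntot, "+",
                       ifelse(npos * 2L < ntot, "-", "mixed")),
      stringsAsFactors = FALSE)
    rec <- rec[rec$frequent_snow_free | rec$frequent_snow_covered, ,
               drop = FALSE]
    rownames(rec) <- NULL
  }
  attr(rec, "min_networks") <- as.integer(min_networks)
  attr(rec, "n_networks") <- c(snow_free = length(networks$snow_free),
                               snow_covered = length(networks$snow_covered))
  class(rec) <- c("association_records", "data.frame")
  rec
}

#' Condition specificity of frequent associations
#'
#' @param records an `association_records` from [frequent_associations()].
#' @return the records with an added `specificity` column in
#'   `{"snow_free_only", "snow_covered_only", "both"}`.
#' @export
condition_specificity <- function(records) {
  stopifnot(inherits(records, "association_records"))
  records$specificity <- ifelse(
    records$frequent_snow_free & records$frequent_snow_covered, "both",
    ifelse(records$frequent_snow_free, "snow_free_only",
           "snow_covered_only"))
  records
}

#' Genus-level summary of frequent fungal-bacterial associations
#'
#' Restricts to fb records frequent in `condition`, drops records lacking a
#' genus annotation on either side, groups by (fungal genus, bacterial
#' genus), and keeps genus pairs supported by at least `min_pair_support`
#' ASV-level associations. The consensus sign is the majority over the
#' member associations' in-condition network occurrences.
#'
#' @param records an `association_records`.
#' @param taxonomy taxonomy `data.frame`.
#' @param condition `"snow_free"` or `"snow_covered"`.
#' @param min_pair_support minimum ASV-level support (default 2, "observed
#'   at least twice").
#' @return `data.frame` with `fungal_genus`, `bacterial_genus`,
#'   `n_supporting`, `n_positive`, `n_negative`, `consensus_sign`.
#' @export
genus_summary <- function(records, taxonomy, condition,
                          min_pair_support = 2L) {
  stopifnot(inherits(records, "association_records"), min_pair_support >= 1L)
  condition <- as.character(normalize_condition(condition))
  freq_col <- paste0("frequent_", condition)
  fb <- records[records$type == "fb" & records[[freq_col]], , drop = FALSE]
  if (!nrow(fb)) {
    return(data.frame(fungal_genus = character(0),
                      bacterial_genus = character(0),
                      n_supporting = integer(0), n_positive = integer(0),
                      n_negative = integer(0), consensus_sign = character(0),
                      stringsAsFactors = FALSE))
  }
  gen <- setNames(taxonomy$genus, taxonomy$asv_id)
  # fb keys are sorted lexicographically; the kingdom tags say which side
  # is the fungal partner
  swap <- fb$kingdom_b == "fungi"
  fungal_id <- ifelse(swap, fb$b, fb$a)
  bact_id <- ifelse(swap, fb$a, fb$b)
  fg <- gen[fungal_id]; bg <- gen[bact_id]
  keep <- !is.na(fg) & !is.na(bg)
  fb <- fb[keep, , drop = FALSE]; fg <- fg[keep]; bg <- bg[keep]
  if (!nrow(fb)) {
    return(genus_summary(records[0, , drop = FALSE], taxonomy, condition,
                         min_pair_support))
  }
  pos_col <- paste0("n_pos_", condition)
  n_col <- paste0("n_", condition)
  grp <- paste(fg, bg, sep = "\r")
  agg <- lapply(split(seq_len(nrow(fb)), grp), function(rows) {
    npos <- sum(fb[[pos_col]][rows])
    ntot <- sum(fb[[n_col]][rows])
    data.frame(
      fungal_genus = fg[rows[1L]], bacterial_genus = bg[rows[1L]],
      n_supporting = length(rows), n_positive = npos,
      n_negative = ntot - npos,
      consensus_sign = if (npos * 2L > ntot) "+" else
        if (npos * 2L < ntot) "-" else "mixed",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  out <- out[out$n_supporting >= min_pair_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recovery of planted associations by the frequent-association consensus
#'
#' Compares, per condition, the frequent fungal-bacterial associations to
#' the planted truth: recall is the fraction of active planted edges
#' recovered, precision the fraction of frequent fb associations that are
#' planted, and sign accuracy the fraction of recovered edges whose
#' in-condition majority sign matches the planted sign.
#'
#' @param records an `association_records`.
#' @param truth the `truth` element of a simulation.
#' @return `data.frame` with one row per condition: `condition`,
#'   `n_truth`, `n_detected`, `n_recovered`, `recall`, `precision`
#'   (`NA` when nothing was detected), `sign_accuracy`.
#' @export
recovery_score <- function(records, truth) {
  stopifnot(inherits(records, "association_records"))
  if (!nrow(truth$edges)) stop("empty truth")
  out <- list()
  for (cond in CONDITIONS) {
    ts <- truth_edge_set(truth, cond)
    freq_col <- paste0("frequent_", cond)
    det <- records[records$type == "fb" & records[[freq_col]], , drop = FALSE]
    det_keys <- edge_key(det$a, det$b)
    hit <- ts %in% det_keys
    n_rec <- sum(hit)
    sign_acc <- NA_real_
    if (n_rec > 0L) {
      pos_col <- paste0("n_pos_", cond)
      n_col <- paste0("n_", cond)
      idx <- match(ts[hit], det_keys)
      maj <- ifelse(det[[pos_col]][idx] * 2L > det[[n_col]][idx], "+",
             ifelse(det[[pos_col]][idx] * 2L < det[[n_col]][idx], "-",
                    "mixed"))
      sign_acc <- mean(maj == names(ts)[hit])
    }
    out[[cond]] <- data.frame(
      condition = cond, n_truth = length(ts), n_detected = nrow(det),
      n_recovered = n_rec,
      recall = n_rec / length(ts),
      precision = if (nrow(det)) n_rec / nrow(det) else NA_real_,
      sign_accuracy = sign_acc, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
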