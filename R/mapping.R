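# Occurrence mapping: resolve each experiment record to positions in the
# reference, with the reappearance ON/OFF semantics, the unmatched-prey
# report, and color cycling over protein sets.

#' Find every occurrence of a prey in the reference
#'
#' Scans the reference for entries whose protein identifier equals
#' `prey_id` exactly (byte-for-byte, case-sensitive). Occurrences are
#' returned in reference-file order: ascending set index, then entry
#' index within the set.
#'
#' @param reference An `apms_reference` tibble.
#' @param prey_id A prey identifier string.
#' @return A tibble with columns `set_index` and `entry_index` (both
#'   1-based), possibly empty when the prey is absent.
#' @export
find_occurrences <- function(reference, prey_id) {
  hit <- reference[reference$protein_id == prey_id,
                   c("set_index", "entry_index")]
  dplyr::arrange(as_tibble(hit), .data$set_index, .data$entry_index)
}

#' Collapse exact duplicate experiment rows
#'
#' Rows identical in all of bait, arc class and prey are collapsed to
#' their first occurrence; later copies would only overdraw the same arc
#' invisibly. Each removal raises a `baitring_warn_duplicate_row`
#' warning.
#'
#' @param experiment An `apms_experiment` tibble.
#' @return A list with `experiment` (the deduplicated records, original
#'   order preserved) and `removals`, a tibble of dropped rows with their
#'   original `record_index`.
#' @export
dedupe_records <- function(experiment) {
  key <- paste(experiment$bait_id, experiment$arc_class, experiment$prey_id,
               sep = "\x1f")
  dup <- duplicated(key)
  removals <- as_tibble(experiment[dup, ])
  removals$record_index <- which(dup)
  removals <- removals[, c("record_index", "bait_id", "arc_class", "prey_id")]
  for (i in seq_len(nrow(removals))) {
    warn(sprintf("duplicate experiment row dropped: %s,%s,%s",
                 removals$bait_id[i], removals$arc_class[i], removals$prey_id[i]),
         class = "baitring_warn_duplicate_row")
  }
  list(experiment = new_experiment(experiment[!dup, ]), removals = removals)
}

#' Map an experiment onto a reference
#'
#' Resolves each experiment record, in file order, to its occurrence(s)
#' in the reference. With the reappearance function ON every occurrence
#' of a matched prey yields an arc (redundant mapping: a prey belonging
#' to several protein sets is drawn once per set). With reappearance OFF
#' only the first occurrence in reference-file order is drawn
#' (non-redundant mapping). Records whose prey is absent from the
#' reference go to the unmatched report, each raising a
#' `baitring_warn_unmatched` warning; absence is never fatal.
#'
#' @param experiment An `apms_experiment` tibble.
#' @param reference An `apms_reference` tibble.
#' @param reappearance Logical; `TRUE` (default) draws all occurrences,
#'   `FALSE` only the first.
#' @param dedupe Collapse exact duplicate rows first (default `TRUE`);
#'   see [dedupe_records()].
#' @return An object of class `apms_mapping`: a list with
#'   \describe{
#'     \item{arcs}{tibble `record_index`, `arc_class`, `prey_id`,
#'       `set_index`, `entry_index`, ordered by record then occurrence.}
#'     \item{unmatched}{tibble `record_index`, `prey_id`.}
#'     \item{removals}{duplicate rows dropped before mapping.}
#'     \item{reappearance}{the flag used.}
#'     \item{n_records}{records mapped (after any deduplication).}
#'   }
#'   `record_index` refers to the (possibly deduplicated) record order.
#' @examples
#' e <- parse_experiment("K,ppi,P1\n")
#' r <- parse_reference(">A\n-,P1,-\n>B\n-,P1,-\n")
#' nrow(map_experiment(e, r, reappearance = TRUE)$arcs)   # 2
#' nrow(map_experiment(e, r, reappearance = FALSE)$arcs)  # 1
#' @export
map_experiment <- function(experiment, reference, reappearance = TRUE,
                           dedupe = TRUE) {
  dd <- if (dedupe) {
    dedupe_records(experiment)
  } else {
    list(experiment = experiment,
         removals = tibble(record_index = integer(), bait_id = character(),
                           arc_class = character(), prey_id = character()))
  }
  recs <- dd$experiment
  arcs <- vector("list", nrow(recs))
  unmatched <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    occ <- find_occurrences(reference, recs$prey_id[i])
    if (nrow(occ) == 0L) {
      warn(sprintf("prey '%s' not found in reference (record %d)",
                   recs$prey_id[i], i),
           class = "baitring_warn_unmatched")
      unmatched[[i]] <- tibble(record_index = i, prey_id = recs$prey_id[i])
    } else {
      if (!reappearance) occ <- occ[1, ]
      arcs[[i]] <- tibble(
        record_index = i,
        arc_class = recs$arc_class[i],
        prey_id = recs$prey_id[i],
        set_index = occ$set_index,
        entry_index = occ$entry_index
      )
    }
  }
  empty_arcs <- tibble(record_index = integer(), arc_class = character(),
                       prey_id = character(), set_index = integer(),
                       entry_index = integer())
  structure(
    list(
      arcs = dplyr::bind_rows(empty_arcs, !!!arcs),
      unmatched = dplyr::bind_rows(
        tibble(record_index = integer(), prey_id = character()), !!!unmatched),
      removals = dd$removals,
      reappearance = reappearance,
      n_records = nrow(recs)
    ),
    class = "apms_mapping"
  )
}

#' Cycle scheme colors over the protein sets
#'
#' Set `k` (1-based) receives scheme color `((k - 1) mod n) + 1`, so a
#' scheme shorter than the number of sets is cycled until every set is
#' colored.
#'
#' @param reference An `apms_reference` tibble.
#' @param scheme An `apms_colors` tibble.
#' @return A tibble `set_index`, `set_name`, `red`, `green`, `blue`, one
#'   row per set in reference order.
#' @export
assign_set_colors <- function(reference, scheme) {
  if (nrow(scheme) == 0L) {
    abort("color scheme is empty", class = "baitring_error")
  }
  sets <- reference_sets(reference)
  idx <- ((sets$set_index - 1L) %% nrow(scheme)) + 1L
  tibble(
    set_index = sets$set_index,
    set_name = sets$set_name,
    red = scheme$red[idx],
    green = scheme$green[idx],
    blue = scheme$blue[idx]
  )
}

#' @export
print.apms_mapping <- function(x, ...) {
  cat(sprintf(
    "<apms_mapping> %d records -> %d arcs (reappearance %s), %d unmatched, %d duplicates dropped\n",
    x$n_records, nrow(x$arcs), if (x$reappearance) "ON" else "OFF",
    nrow(x$unmatched), nrow(x$removals)
  ))
  invisible(x)
}

#' Tidy an occurrence mapping
#'
#' `tidy()` returns the per-arc table; `glance()` a one-row summary.
#'
#' @param x An `apms_mapping` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy apms_mapping
#' @export
tidy.apms_mapping <- function(x, ...) x$arcs

#' @rdname tidy.apms_mapping
#' @method glance apms_mapping
#' @export
glance.apms_mapping <- function(x, ...) {
  tibble(
    n_records = x$n_records,
    n_arcs = nrow(x$arcs),
    n_unmatched = nrow(x$unmatched),
    n_duplicates_dropped = nrow(x$removals),
    reappearance = x$reappearance
  )
}
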