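# Seeded synthetic fixture generator: emits a parseable experiment /
# reference / color-scheme trio with controlled overlap structure, and
# records ground-truth pipeline counts at generation time so tests can
# compare the mapping pipeline against construction.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_fixed_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic AP-MS fixture
#'
#' Defaults emulate a moderately sized kinase AP-MS study: four protein
#' sets of eight preys each (the scale of a lenticular multi-bait
#' reference), sixteen experiment records (twelve interaction, four
#' kinase-substrate), a fifth of reference entries shared between sets,
#' and a tenth of experiment preys absent from the reference.
#'
#' @param n_sets Number of protein sets in the reference.
#' @param set_sizes Integer vector of per-set sizes (recycled to
#'   `n_sets`), or `NULL` to sample each size uniformly from 4 to 12.
#' @param n_ppi,n_ivtk Number of `ppi` / `ivtk` experiment records.
#' @param cross_set_duplication Fraction in `[0, 1]` of reference
#'   entries that are duplicates of an entry in another set.
#' @param unmatched_fraction Fraction in `[0, 1]` of experiment preys
#'   absent from the reference.
#' @param n_duplicate_rows Exact duplicate experiment rows appended
#'   (default 0); ground truth for the deduplication report.
#' @param n_colors Colors in the generated scheme (default 5; fewer
#'   colors than sets exercises color cycling).
#' @param seed Integer seed; the same spec always yields byte-identical
#'   fixture files.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_sets = 4, set_sizes = c(8, 8, 8, 8), n_ppi = 12,
                         n_ivtk = 4, cross_set_duplication = 0.2,
                         unmatched_fraction = 0.1, n_duplicate_rows = 0,
                         n_colors = 5, seed = 1) {
  stopifnot(
    n_sets >= 1, n_ppi >= 0, n_ivtk >= 0,
    cross_set_duplication >= 0, cross_set_duplication <= 1,
    unmatched_fraction >= 0, unmatched_fraction <= 1,
    n_duplicate_rows >= 0, n_colors >= 1,
    is.numeric(seed), length(seed) == 1L
  )
  if (!is.null(set_sizes)) {
    set_sizes <- rep_len(as.integer(set_sizes), n_sets)
    stopifnot(all(set_sizes >= 0))
  }
  structure(
    list(n_sets = as.integer(n_sets), set_sizes = set_sizes,
         n_ppi = as.integer(n_ppi), n_ivtk = as.integer(n_ivtk),
         cross_set_duplication = cross_set_duplication,
         unmatched_fraction = unmatched_fraction,
         n_duplicate_rows = as.integer(n_duplicate_rows),
         n_colors = as.integer(n_colors), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic fixture trio with recorded ground truth
#'
#' Builds the three input files as text plus a `truth` record computed
#' by construction (occurrence counts are tallied directly from the
#' generated reference, independently of the mapping pipeline):
#' `expected_on_arcs`, `expected_off_arcs`, `expected_unmatched`,
#' `duplicate_rows_injected`.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `apms_fixture` with elements
#'   `experiment_text`, `reference_text`, `colors_text`, `truth` and
#'   `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixed_seed(spec$seed, {
    sizes <- spec$set_sizes %||% sample(4:12, spec$n_sets, replace = TRUE)
    total <- sum(sizes)
    n_exp <- spec$n_ppi + spec$n_ivtk
    if (total == 0L && n_exp > 0L && spec$unmatched_fraction < 1) {
      abort("infeasible fixture: experiment records requested but the reference has no entries",
            class = "baitring_error")
    }

    # Reference: fresh unique identifiers per slot, then convert a
    # fraction of slots in sets 2..n into duplicates of an identifier
    # from another set (never duplicating within a set).
    ids <- sprintf("P%05d", sample.int(90000L, total))
    set_of <- rep(seq_along(sizes), times = sizes)
    set_fct <- factor(set_of, levels = seq_len(spec$n_sets))
    sets <- unname(split(ids, set_fct))
    n_dup <- round(spec$cross_set_duplication * total)
    if (n_dup > 0L && spec$n_sets >= 2L) {
      candidates <- which(set_of > 1L)
      chosen <- sample(candidates, min(n_dup, length(candidates)))
      flat <- ids
      for (slot in chosen) {
        s <- set_of[slot]
        pool <- setdiff(flat[set_of != s], flat[set_of == s])
        if (length(pool) == 0L) next
        flat[slot] <- pool[sample.int(length(pool), 1L)]
      }
      ids <- flat
      sets <- unname(split(ids, set_fct))
    }
    set_names <- sprintf("Set %02d", seq_len(spec$n_sets))
    ref_lines <- unlist(purrr::map(seq_len(spec$n_sets), function(k) {
      members <- sets[[k]]
      c(paste0(">", set_names[k]),
        if (length(members)) paste0("protein ", members, ",", members, ",annotated"))
    }))
    reference_text <- paste0(paste0(ref_lines, collapse = "\n"), "\n")

    # Experiment: distinct matched preys sampled from the reference,
    # plus fresh identifiers guaranteed absent.
    n_unmatched <- round(spec$unmatched_fraction * n_exp)
    n_matched <- n_exp - n_unmatched
    uniq_ids <- unique(ids)
    if (n_matched > length(uniq_ids)) {
      abort(sprintf(
        "infeasible fixture: %d matched preys requested but only %d distinct reference proteins",
        n_matched, length(uniq_ids)), class = "baitring_error")
    }
    matched <- if (n_matched > 0L) sample(uniq_ids, n_matched) else character()
    absent <- sprintf("X%05d", sample.int(90000L, n_unmatched) + 90000L)
    preys <- sample(c(matched, absent))
    classes <- sample(c(rep("ppi", spec$n_ppi), rep("ivtk", spec$n_ivtk)))
    bait <- "BAIT01"
    rows <- paste(bait, classes, preys, sep = ",")
    if (spec$n_duplicate_rows > 0L) {
      if (n_exp == 0L) {
        abort("infeasible fixture: duplicate rows requested with no base records",
              class = "baitring_error")
      }
      dup_rows <- rows[sample.int(length(rows), spec$n_duplicate_rows,
                                  replace = TRUE)]
      rows <- c(rows, dup_rows)
    }
    experiment_text <- paste0(paste0(rows, collapse = "\n"), "\n")

    # Colors: random RGB triples.
    colors_text <- paste0(paste(
      sample(0:255, spec$n_colors, replace = TRUE),
      sample(0:255, spec$n_colors, replace = TRUE),
      sample(0:255, spec$n_colors, replace = TRUE), sep = ","),
      collapse = "\n")
    colors_text <- paste0(colors_text, "\n")

    # Ground truth by construction: occurrence counts tallied straight
    # from the generated identifier multiset.
    occ <- table(ids)
    truth <- list(
      expected_on_arcs = if (n_matched) sum(occ[matched]) else 0L,
      expected_off_arcs = n_matched,
      expected_unmatched = n_unmatched,
      duplicate_rows_injected = spec$n_duplicate_rows
    )
    structure(
      list(experiment_text = experiment_text,
           reference_text = reference_text,
           colors_text = colors_text,
           truth = truth, spec = spec),
      class = "apms_fixture"
    )
  })
}

#' @export
print.apms_fixture <- function(x, ...) {
  cat(sprintf(
    "<apms_fixture> seed %d: %d sets, %d records (truth: ON %d / OFF %d arcs, %d unmatched, %d dup rows)\n",
    x$spec$seed, x$spec$n_sets, x$spec$n_ppi + x$spec$n_ivtk,
    x$truth$expected_on_arcs, x$truth$expected_off_arcs,
    x$truth$expected_unmatched, x$truth$duplicate_rows_injected
  ))
  invisible(x)
}

#' Write a generated fixture trio to a directory
#'
#' @param fixture An `apms_fixture` from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    experiment = file.path(dir, "experiment.csv"),
    reference = file.path(dir, "reference.csv"),
    colors = file.path(dir, "colors.csv")
  )
  emit_text(fixture$experiment_text, paths[["experiment"]])
  emit_text(fixture$reference_text, paths[["reference"]])
  emit_text(fixture$colors_text, paths[["colors"]])
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}
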