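# Shared helpers: tiny input builders and independent brute-force
# oracles that the mapping and layout implementations are checked
# against.

exp_text <- function(bait, classes, preys) {
  paste0(paste(bait, classes, preys, sep = ","), "\n", collapse = "")
}

ref_text <- function(sets) {
  # sets: named list of character vectors of protein ids
  paste0(unlist(lapply(names(sets), function(nm) {
    c(paste0(">", nm, "\n"),
      if (length(sets[[nm]])) paste0("l,", sets[[nm]], ",r\n"))
  })), collapse = "")
}

# Independent quadratic scan: every (set, entry) position whose id
# equals the query, in file order. Works on the parsed reference but
# only via an explicit double loop, not via find_occurrences.
brute_occurrences <- function(reference, prey_id) {
  sets <- reference_sets(reference)
  out <- list()
  for (s in sets$set_index) {
    block <- reference[reference$set_index == s, ]
    for (j in seq_len(nrow(block))) {
      if (identical(block$protein_id[j], prey_id)) {
        out[[length(out) + 1L]] <- c(s, block$entry_index[j])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(set_index = integer(), entry_index = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(set_index = m[, 1], entry_index = m[, 2])
}

# Brute-force re-mapping of a whole experiment, mirroring the stated
# semantics directly (per-record loop over brute_occurrences).
brute_map <- function(experiment, reference, reappearance) {
  key <- paste(experiment$bait_id, experiment$arc_class, experiment$prey_id)
  recs <- experiment[!duplicated(key), ]
  arcs <- list(); unmatched <- list()
  for (i in seq_len(nrow(recs))) {
    occ <- brute_occurrences(reference, recs$prey_id[i])
    if (nrow(occ) == 0L) {
      unmatched[[length(unmatched) + 1L]] <- data.frame(
        record_index = i, prey_id = recs$prey_id[i])
    } else {
      if (!reappearance) occ <- occ[1, , drop = FALSE]
      arcs[[length(arcs) + 1L]] <- data.frame(
        record_index = i, arc_class = recs$arc_class[i],
        prey_id = recs$prey_id[i],
        set_index = occ$set_index, entry_index = occ$entry_index)
    }
  }
  list(
    arcs = if (length(arcs)) do.call(rbind, arcs) else
      data.frame(record_index = integer(), arc_class = character(),
                 prey_id = character(), set_index = integer(),
                 entry_index = integer()),
    unmatched = if (length(unmatched)) do.call(rbind, unmatched) else
      data.frame(record_index = integer(), prey_id = character())
  )
}

quiet_map <- function(...) suppressWarnings(map_experiment(...))
quiet_diagram <- function(...) suppressWarnings(build_diagram(...))
quiet_segments <- function(...) suppressWarnings(compute_segments(...))

withr_like_tempdir <- function() {
  d <- tempfile("baitring-test-")
  dir.create(d)
  d
}
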