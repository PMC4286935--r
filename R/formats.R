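# Readers and writers for the three comma-delimited input dialects:
# experiment (bait, arc class, prey), FASTA-like protein-set reference,
# and RGB color scheme. All parsers preserve file order exactly.

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

arc_classes <- c("ppi", "ivtk")

# Split input into lines, tolerate CRLF, strip a leading BOM, and keep
# original line numbers so errors can point at the offending line.
prep_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- sub("\r$", "", text)
  bom <- intToUtf8(0xFEFF)
  if (length(text) > 0L && startsWith(text[1], bom)) {
    text[1] <- substring(text[1], 2L)
  }
  keep <- !grepl("^[[:space:]]*$", text)
  tibble(line = which(keep), text = text[keep])
}

# Split one line on literal commas. No quoting dialect: commas inside
# fields are not representable. Trailing empty fields are preserved
# (base strsplit drops them).
split_csv_fields <- function(s) {
  parts <- strsplit(paste0(s, "\x01"), ",", fixed = TRUE)[[1]]
  parts[length(parts)] <- sub("\x01$", "", parts[length(parts)])
  trimws(parts)
}

parse_error <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("line %d: %s", line, msg)
  abort(msg, class = "baitring_parse_error")
}

require_n_fields <- function(fields, n, line) {
  if (length(fields) != n) {
    parse_error(sprintf("expected %d comma-delimited fields, found %d", n, length(fields)), line)
  }
  fields
}

#' Parse an AP-MS experiment file
#'
#' An experiment file holds one bait protein and its classed interactions,
#' one per row, as three comma-delimited columns: bait identifier, arc
#' class (`"ppi"` for a colored protein-protein interaction arc, `"ivtk"`
#' for a black in vitro kinase substrate arc), and prey identifier.
#' Identifiers are compared byte-for-byte elsewhere in the package, so
#' only surrounding whitespace is stripped; case is preserved.
#'
#' @param text A single string, or a character vector of lines (e.g. from
#'   [readLines()]). Blank lines are skipped; CRLF endings and a leading
#'   byte-order mark are tolerated.
#' @return A tibble of class `apms_experiment` with columns `bait_id`,
#'   `arc_class` and `prey_id`, one row per record, in file order.
#' @examples
#' parse_experiment("SRPK1,ppi,P78362\nSRPK1,ivtk,Q13523\n")
#' @seealso [read_experiment()], [write_experiment()]
#' @export
parse_experiment <- function(text) {
  rows <- prep_lines(text)
  if (nrow(rows) == 0L) parse_error("no records in experiment file")
  recs <- purrr::map2(rows$text, rows$line, function(txt, ln) {
    f <- require_n_fields(split_csv_fields(txt), 3L, ln)
    if (f[1] == "") parse_error("empty bait identifier", ln)
    if (f[3] == "") parse_error("empty prey identifier", ln)
    if (!f[2] %in% arc_classes) {
      parse_error(sprintf("arc class must be 'ppi' or 'ivtk', found '%s'", f[2]), ln)
    }
    f
  })
  out <- tibble(
    bait_id = purrr::map_chr(recs, 1),
    arc_class = purrr::map_chr(recs, 2),
    prey_id = purrr::map_chr(recs, 3)
  )
  baits <- unique(out$bait_id)
  if (length(baits) > 1L) {
    parse_error(sprintf(
      "multiple baits in one experiment file: %s",
      paste(baits, collapse = ", ")
    ))
  }
  new_experiment(out)
}

new_experiment <- function(df) {
  structure(as_tibble(df), class = c("apms_experiment", class(tibble())))
}

#' Bait identifier of an experiment
#'
#' @param experiment An `apms_experiment` tibble.
#' @return The single bait identifier string.
#' @export
experiment_bait <- function(experiment) {
  unique(experiment$bait_id)[1]
}

#' Parse a protein-set reference file
#'
#' The reference file groups annotated proteins into named, ordered
#' *protein sets*, in a FASTA-like dialect: a line starting with `>` opens
#' a set named by the rest of the line; subsequent rows carry three
#' comma-delimited columns `description, protein identifier, description`.
#' Column 2 is the identifier that experiment prey identifiers are mapped
#' against. The same identifier may legally occur in several sets; that
#' cross-set redundancy is what the reappearance mapping mode exposes.
#'
#' @inheritParams parse_experiment
#' @return A tibble of class `apms_reference` with columns `set_index`,
#'   `set_name`, `entry_index` (1-based within the set), `desc_left`,
#'   `protein_id`, `desc_right`, in file order. The full ordered vector of
#'   set names (including empty sets, which warn) is kept in the
#'   `set_names` attribute; see [reference_sets()].
#' @examples
#' ref <- parse_reference(">U1 snRNP\nkinase,Q96SB4,splicing\n>tri-snRNP\n-,Q13523,-\n")
#' reference_sets(ref)
#' @export
parse_reference <- function(text) {
  rows <- prep_lines(text)
  if (nrow(rows) == 0L) parse_error("no protein sets in reference file")
  set_names <- character()
  entries <- list()
  current <- 0L
  entry_n <- 0L
  for (i in seq_len(nrow(rows))) {
    txt <- rows$text[i]
    ln <- rows$line[i]
    if (startsWith(txt, ">")) {
      if (current > 0L && entry_n == 0L) {
        warn(sprintf("protein set '%s' has no entries", set_names[current]),
             class = "baitring_warn_empty_set")
      }
      nm <- trimws(substring(txt, 2L))
      if (nm == "") parse_error("protein set name must be non-empty", ln)
      set_names <- c(set_names, nm)
      current <- current + 1L
      entry_n <- 0L
    } else {
      if (current == 0L) parse_error("data row before any '>' set header", ln)
      f <- require_n_fields(split_csv_fields(txt), 3L, ln)
      if (f[2] == "") parse_error("empty protein identifier", ln)
      entry_n <- entry_n + 1L
      entries[[length(entries) + 1L]] <- tibble(
        set_index = current, entry_index = entry_n,
        desc_left = f[1], protein_id = f[2], desc_right = f[3]
      )
    }
  }
  if (current > 0L && entry_n == 0L) {
    warn(sprintf("protein set '%s' has no entries", set_names[current]),
         class = "baitring_warn_empty_set")
  }
  body <- if (length(entries)) dplyr::bind_rows(entries) else
    tibble(set_index = integer(), entry_index = integer(),
           desc_left = character(), protein_id = character(),
           desc_right = character())
  body$set_name <- set_names[body$set_index]
  body <- body[, c("set_index", "set_name", "entry_index",
                   "desc_left", "protein_id", "desc_right")]
  new_reference(body, set_names)
}

new_reference <- function(df, set_names) {
  structure(as_tibble(df),
            set_names = set_names,
            class = c("apms_reference", class(tibble())))
}

#' Summarise the protein sets of a reference
#'
#' @param reference An `apms_reference` tibble.
#' @return A tibble with one row per set (`set_index`, `set_name`,
#'   `n_entries`), in file order, including empty sets.
#' @export
reference_sets <- function(reference) {
  nms <- attr(reference, "set_names")
  counts <- tabulate(reference$set_index, nbins = length(nms))
  tibble(set_index = seq_along(nms), set_name = nms, n_entries = counts)
}

#' Parse an RGB color scheme file
#'
#' One color per line as three comma-delimited integers in `[0, 255]`
#' (red, green, blue). When a reference holds more protein sets than the
#' scheme holds colors, colors are cycled over the sets in order; see
#' [assign_set_colors()].
#'
#' @inheritParams parse_experiment
#' @return A tibble of class `apms_colors` with integer columns `red`,
#'   `green`, `blue`, in file order.
#' @examples
#' parse_color_scheme("255,0,0\n0,0,255\n")
#' @export
parse_color_scheme <- function(text) {
  rows <- prep_lines(text)
  if (nrow(rows) == 0L) parse_error("no colors in color scheme file")
  cols <- purrr::map2(rows$text, rows$line, function(txt, ln) {
    f <- require_n_fields(split_csv_fields(txt), 3L, ln)
    if (!all(grepl("^-?[0-9]+$", f))) {
      parse_error(sprintf("color components must be integers, found '%s'", txt), ln)
    }
    v <- as.integer(f)
    if (any(v < 0L | v > 255L)) {
      parse_error(sprintf("color component out of range [0, 255]: '%s'", txt), ln)
    }
    v
  })
  new_color_scheme(tibble(
    red = purrr::map_int(cols, 1),
    green = purrr::map_int(cols, 2),
    blue = purrr::map_int(cols, 3)
  ))
}

new_color_scheme <- function(df) {
  structure(as_tibble(df), class = c("apms_colors", class(tibble())))
}

check_no_commas <- function(x, what) {
  bad <- grepl(",", x, fixed = TRUE)
  if (any(bad)) {
    abort(sprintf("%s may not contain commas: '%s'", what, x[which(bad)[1]]),
          class = "baitring_write_error")
  }
  invisible(x)
}

#' Serialize parsed inputs back to their file dialects
#'
#' Each writer emits newline-terminated, LF-delimited text such that
#' `parse_*(write_*(x))` reproduces `x` field-for-field. Pass `path` to
#' also write the text to a file.
#'
#' @param experiment,reference,scheme A parsed `apms_experiment`,
#'   `apms_reference` or `apms_colors` object.
#' @param path Optional file path; when given, the text is written there.
#' @return The serialized text, invisibly when `path` is given.
#' @export
write_experiment <- function(experiment, path = NULL) {
  if (nrow(experiment) == 0L) {
    abort("refusing to write an experiment with no records",
          class = "baitring_write_error")
  }
  check_no_commas(experiment$bait_id, "bait_id")
  check_no_commas(experiment$prey_id, "prey_id")
  txt <- paste0(paste(experiment$bait_id, experiment$arc_class,
                      experiment$prey_id, sep = ","),
                collapse = "\n")
  emit_text(paste0(txt, "\n"), path)
}

#' @rdname write_experiment
#' @export
write_reference <- function(reference, path = NULL) {
  sets <- reference_sets(reference)
  if (nrow(sets) == 0L) {
    abort("refusing to write a reference with no sets", class = "baitring_write_error")
  }
  check_no_commas(reference$desc_left, "description")
  check_no_commas(reference$desc_right, "description")
  check_no_commas(reference$protein_id, "protein_id")
  blocks <- purrr::map_chr(sets$set_index, function(k) {
    body <- reference[reference$set_index == k, ]
    lines <- c(paste0(">", sets$set_name[k]),
               paste(body$desc_left, body$protein_id, body$desc_right, sep = ","))
    paste0(lines, collapse = "\n")
  })
  emit_text(paste0(paste0(blocks, collapse = "\n"), "\n"), path)
}

#' @rdname write_experiment
#' @export
write_color_scheme <- function(scheme, path = NULL) {
  if (nrow(scheme) == 0L) {
    abort("refusing to write an empty color scheme", class = "baitring_write_error")
  }
  txt <- paste0(paste(scheme$red, scheme$green, scheme$blue, sep = ","),
                collapse = "\n")
  emit_text(paste0(txt, "\n"), path)
}

emit_text <- function(text, path) {
  if (is.null(path)) return(text)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(text, con, eos = NULL)
  invisible(text)
}

#' Read the input dialects from files
#'
#' Convenience wrappers around the `parse_*()` functions.
#'
#' @param path Path to a file.
#' @return The corresponding parsed object.
#' @export
read_experiment <- function(path) parse_experiment(readLines(path, warn = FALSE))

#' @rdname read_experiment
#' @export
read_reference <- function(path) parse_reference(readLines(path, warn = FALSE))

#' @rdname read_experiment
#' @export
read_color_scheme <- function(path) parse_color_scheme(readLines(path, warn = FALSE))
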