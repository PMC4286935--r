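test_that("find_occurrences returns reference-order positions, empty on absence", {
  r <- parse_reference(ref_text(list(A = c("P1", "P2"), B = "P1")))
  occ <- find_occurrences(r, "P1")
  expect_equal(occ$set_index, c(1L, 2L))
  expect_equal(occ$entry_index, c(1L, 1L))
  expect_equal(nrow(find_occurrences(r, "ZZZ")), 0L)
})

test_that("find_occurrences agrees with a brute-force scan on random references", {
  fx <- generate_fixture(fixture_spec(n_sets = 5, set_sizes = c(20, 20, 20, 20, 20),
                                      cross_set_duplication = 0.2, seed = 11))
  r <- parse_reference(fx$reference_text)
  queries <- c(unique(r$protein_id), "ABSENT1", "ABSENT2")
  for (q in queries) {
    got <- find_occurrences(r, q)
    want <- brute_occurrences(r, q)
    expect_equal(got$set_index, want$set_index)
    expect_equal(got$entry_index, want$entry_index)
  }
})

test_that("reappearance ON draws every occurrence, OFF only the first", {
  e <- parse_experiment("K,ppi,P1\n")
  r <- parse_reference(ref_text(list(A = "P1", B = "P1")))
  on <- map_experiment(e, r, reappearance = TRUE)
  expect_equal(nrow(on$arcs), 2L)
  expect_equal(on$arcs$set_index, c(1L, 2L))
  off <- map_experiment(e, r, reappearance = FALSE)
  expect_equal(nrow(off$arcs), 1L)
  expect_equal(off$arcs$set_index, 1L)
  expect_equal(off$arcs$entry_index, 1L)
})

test_that("unmatched preys are reported, warned about, and never fatal", {
  e <- parse_experiment("K,ppi,X\n")
  r <- parse_reference(ref_text(list(A = "P1")))
  expect_warning(m <- map_experiment(e, r), class = "baitring_warn_unmatched")
  expect_equal(nrow(m$arcs), 0L)
  expect_equal(m$unmatched$record_index, 1L)
  expect_equal(m$unmatched$prey_id, "X")
})

test_that("every record lands in arcs or unmatched, never both; OFF subset of ON", {
  for (seed in c(11, 12, 13)) {
    fx <- generate_fixture(fixture_spec(n_sets = 5, set_sizes = c(6, 8, 10, 7, 9),
                                        n_ppi = 15, n_ivtk = 5,
                                        cross_set_duplication = 0.2,
                                        unmatched_fraction = 0.15, seed = seed))
    e <- parse_experiment(fx$experiment_text)
    r <- parse_reference(fx$reference_text)
    on <- quiet_map(e, r, reappearance = TRUE)
    off <- quiet_map(e, r, reappearance = FALSE)

    # conservation: |OFF arcs| + |unmatched| = |deduped records|
    expect_equal(nrow(off$arcs) + nrow(off$unmatched), off$n_records)
    # OFF records contribute at most one arc
    expect_false(any(duplicated(off$arcs$record_index)))
    # partition: a record is mapped xor unmatched
    expect_length(intersect(on$arcs$record_index, on$unmatched$record_index), 0)
    expect_setequal(c(on$arcs$record_index, on$unmatched$record_index),
                    seq_len(on$n_records))
    # containment: the OFF arc set is a subset of the ON arc set
    key <- function(a) paste(a$record_index, a$set_index, a$entry_index)
    expect_true(all(key(off$arcs) %in% key(on$arcs)))
    expect_gte(nrow(on$arcs), nrow(off$arcs))
    # ON arc count equals the sum of brute-force occurrence counts
    bm <- brute_map(e, r, reappearance = TRUE)
    expect_equal(nrow(on$arcs), nrow(bm$arcs))
  }
})

test_that("mapping agrees position-for-position with the brute-force oracle", {
  for (seed in c(21, 22)) {
    fx <- generate_fixture(fixture_spec(n_sets = 4, set_sizes = c(12, 9, 14, 8),
                                        n_ppi = 14, n_ivtk = 6,
                                        cross_set_duplication = 0.25,
                                        unmatched_fraction = 0.1, seed = seed))
    e <- parse_experiment(fx$experiment_text)
    r <- parse_reference(fx$reference_text)
    for (reapp in c(TRUE, FALSE)) {
      got <- quiet_map(e, r, reappearance = reapp)
      want <- brute_map(e, r, reappearance = reapp)
      expect_equal(as.data.frame(got$arcs), want$arcs,
                   ignore_attr = TRUE)
      expect_equal(as.data.frame(got$unmatched), want$unmatched,
                   ignore_attr = TRUE)
    }
  }
})

test_that("mapping is deterministic", {
  fx <- generate_fixture(fixture_spec(seed = 31))
  e <- parse_experiment(fx$experiment_text)
  r <- parse_reference(fx$reference_text)
  m1 <- quiet_map(e, r, TRUE)
  m2 <- quiet_map(e, r, TRUE)
  expect_identical(m1$arcs, m2$arcs)
  expect_identical(m1$unmatched, m2$unmatched)
})

test_that("dedupe collapses only exact (bait, class, prey) duplicates", {
  e <- parse_experiment("K,ppi,A\nK,ppi,A\n")
  expect_warning(dd <- dedupe_records(e), class = "baitring_warn_duplicate_row")
  expect_equal(nrow(dd$experiment), 1L)
  expect_equal(dd$removals$record_index, 2L)

  e2 <- parse_experiment("K,ppi,A\nK,ivtk,A\n")
  dd2 <- dedupe_records(e2)
  expect_equal(nrow(dd2$experiment), 2L)
  expect_equal(nrow(dd2$removals), 0L)
})

test_that("dedupe removal count equals the injected duplicate count", {
  fx <- generate_fixture(fixture_spec(seed = 3, n_duplicate_rows = 5))
  e <- parse_experiment(fx$experiment_text)
  dd <- suppressWarnings(dedupe_records(e))
  expect_equal(nrow(dd$removals), fx$truth$duplicate_rows_injected)
})

test_that("set colors cycle modulo the scheme length", {
  r5 <- parse_reference(ref_text(list(A = "a", B = "b", C = "c", D = "d", E = "e")))
  s2 <- parse_color_scheme("10,20,30\n40,50,60\n")
  got <- assign_set_colors(r5, s2)
  expect_equal(got$red, c(10L, 40L, 10L, 40L, 10L))

  r2 <- parse_reference(ref_text(list(A = "a", B = "b")))
  s5 <- parse_color_scheme("1,1,1\n2,2,2\n3,3,3\n4,4,4\n5,5,5\n")
  expect_equal(assign_set_colors(r2, s5)$red, c(1L, 2L))

  r1 <- parse_reference(ref_text(list(A = "a")))
  s1 <- parse_color_scheme("7,8,9\n")
  expect_equal(assign_set_colors(r1, s1)$blue, 9L)
})

test_that("tidy and glance summarise a mapping", {
  e <- parse_experiment("K,ppi,P1\nK,ppi,P1\nK,ivtk,X\n")
  r <- parse_reference(ref_text(list(A = "P1", B = "P1")))
  m <- suppressWarnings(map_experiment(e, r, TRUE))
  expect_equal(nrow(tidy(m)), 2L)
  g <- glance(m)
  expect_equal(g$n_records, 2L)
  expect_equal(g$n_unmatched, 1L)
  expect_equal(g$n_duplicates_dropped, 1L)
})
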