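mk_hits <- function(identity, coverage, bit_score,
                    query = sprintf("q%d", seq_along(identity)),
                    subject = sprintf("S%d", seq_along(identity)),
                    e_value = rep(1e-10, length(identity))) {
  data.frame(query_id = query, subject_id = subject, identity = identity,
             coverage = coverage, bit_score = bit_score, e_value = e_value,
             stringsAsFactors = FALSE)
}

test_that("threshold bounds are inclusive and conjunctive", {
  h <- mk_hits(identity = c(40.0, 39.9), coverage = c(40.0, 90),
               bit_score = c(30.0, 200))
  out <- filter_hits(h)
  expect_equal(out$query_id, "q1")   # boundary row retained, 39.9 removed
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("filter_hits matches an exhaustive row-by-row check", {
  h <- random_hit_table(50, seed = 11)
  out <- filter_hits(h, 40, 40, 30)
  keep <- vapply(seq_len(nrow(h)), function(i)
    h$identity[i] >= 40 && h$coverage[i] >= 40 && h$bit_score[i] >= 30,
    logical(1))
  expect_equal(out, h[keep, ], ignore_attr = TRUE)
})

test_that("best-hit resolution keeps the top scorer per subject", {
  h1 <- mk_hits(85, 80, 120)
  expect_equal(select_best_hits(h1), h1, ignore_attr = TRUE)

  h2 <- mk_hits(c(85, 90), c(80, 80), c(55, 80), subject = c("S1", "S1"))
  expect_equal(select_best_hits(h2)$bit_score, 80)

  # planted ties resolved by e-value then query id, against a per-subject scan
  set.seed(5)
  h3 <- mk_hits(identity = rep(80, 30), coverage = rep(80, 30),
                bit_score = sample(c(50, 60, 70), 30, replace = TRUE),
                subject = sprintf("S%d", sample.int(8, 30, replace = TRUE)),
                e_value = sample(c(1e-20, 1e-10), 30, replace = TRUE))
  got <- select_best_hits(h3)
  for (s in unique(h3$subject_id)) {
    rows <- h3[h3$subject_id == s, , drop = FALSE]
    rows <- rows[rows$bit_score == max(rows$bit_score), , drop = FALSE]
    rows <- rows[rows$e_value == min(rows$e_value), , drop = FALSE]
    want <- rows[rows$query_id == min(rows$query_id), , drop = FALSE][1L, ]
    expect_equal(got[got$subject_id == s, ], want, ignore_attr = TRUE)
  }
})

test_that("best-hit resolution is idempotent and order-invariant", {
  set.seed(9)
  h <- random_hit_table(40, seed = 9)
  once <- select_best_hits(h)
  expect_equal(select_best_hits(once), once, ignore_attr = TRUE)
  perm <- h[sample.int(nrow(h)), , drop = FALSE]
  expect_equal(select_best_hits(perm), once, ignore_attr = TRUE)
})

test_that("the TPM floor removes strictly sub-threshold transcripts", {
  h <- mk_hits(c(80, 80), c(80, 80), c(100, 100))
  expr <- data.frame(transcript_id = c("q1", "q2"), tpm = c(0.5, 0.49),
                     stringsAsFactors = FALSE)
  out <- apply_tpm_floor(h, expr)
  expect_equal(out$query_id, "q1")   # exactly 0.5 survives
  expect_equal(out$tpm, 0.5)

  expr_missing <- expr[1L, , drop = FALSE]
  expect_error(apply_tpm_floor(h, expr_missing), "q2")

  # mixed table vs brute force
  h10 <- random_hit_table(10, seed = 21)
  e10 <- random_expression_for(h10, seed = 22)
  out10 <- apply_tpm_floor(h10, e10, 0.5)
  want <- h10[e10$tpm[match(h10$query_id, e10$transcript_id)] >= 0.5, ]
  expect_equal(out10$query_id, want$query_id)
})

test_that("filter and TPM floor commute", {
  h <- random_hit_table(60, seed = 31)
  e <- random_expression_for(h, seed = 32)
  a <- apply_tpm_floor(filter_hits(h), e)
  b <- filter_hits(apply_tpm_floor(h, e))
  expect_equal(a$query_id, b$query_id)
  expect_equal(a$tpm, b$tpm)
})

test_that("family relative expression is the member mean TPM", {
  h <- data.frame(query_id = sprintf("q%d", 1:4),
                  subject_id = sprintf("S%d", 1:4),
                  tpm = c(10, 20, 30, 7.3),
                  family = c("famA", "famA", "famA", "famB"),
                  stringsAsFactors = FALSE)
  prof <- family_relative_expression(h)
  expect_equal(prof$relative_expression[prof$family == "famA"], 20)
  expect_equal(prof$relative_expression[prof$family == "famB"], 7.3)
  expect_equal(prof$n_hits, c(3L, 1L))

  # 5 random families recomputed through an independent split/mean path
  set.seed(41)
  h2 <- data.frame(query_id = sprintf("q%d", 1:40),
                   subject_id = sprintf("S%d", 1:40),
                   tpm = round(stats::rlnorm(40, 1), 4),
                   family = sample(sprintf("fam%d", 1:5), 40, replace = TRUE),
                   stringsAsFactors = FALSE)
  prof2 <- family_relative_expression(h2)
  want <- vapply(split(h2$tpm, h2$family), mean, numeric(1))
  expect_equal(stats::setNames(prof2$relative_expression, prof2$family),
               want[prof2$family])
  # member counts add up to the number of family-annotated hits
  expect_equal(sum(prof2$n_hits), nrow(h2))
})

test_that("hits without family attribution are set aside, not aggregated", {
  h <- data.frame(query_id = c("q1", "q2"), subject_id = c("S1", "S2"),
                  tpm = c(5, 9), family = c("famA", ""),
                  stringsAsFactors = FALSE)
  prof <- family_relative_expression(h)
  expect_equal(prof$family, "famA")
  expect_equal(attr(prof, "unassigned")$query_id, "q2")
})

test_that("superfamily collapsing happens before aggregation", {
  h <- data.frame(query_id = c("q1", "q2"), subject_id = c("S1", "S2"),
                  tpm = c(10, 30), family = c("famA1", "famA2"),
                  stringsAsFactors = FALSE)
  sf <- data.frame(family = c("famA1", "famA2"), superfamily = "famA",
                   stringsAsFactors = FALSE)
  prof <- family_relative_expression(h, superfamily_map = sf)
  expect_equal(prof$family, "famA")
  expect_equal(prof$relative_expression, 20)
})

test_that("peptide fraction counts short non-fragment subjects", {
  h <- data.frame(length_aa = rep(60L, 5), is_fragment = FALSE)
  expect_equal(peptide_fraction(h), 0)

  h2 <- data.frame(length_aa = c(rep(30L, 2), rep(100L, 8)),
                   is_fragment = FALSE)
  expect_equal(peptide_fraction(h2), 0.2)

  # fragments are excluded from numerator and denominator
  h3 <- data.frame(length_aa = c(30, 30, 45, 100, 100, 100),
                   is_fragment = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(peptide_fraction(h3), 1 / 4)
  expect_equal(peptide_fraction(h3, ignore_fragments = FALSE), 3 / 6)

  expect_true(is.na(peptide_fraction(h3[h3$is_fragment, ])))
})

test_that("overlap report handles degenerate and planted structures", {
  prof <- function(fams, n = 2L) data.frame(
    family = fams, n_hits = rep(n, length(fams)),
    relative_expression = 1, stringsAsFactors = FALSE)

  same <- list(a = prof(c("f1", "f2")), b = prof(c("f1", "f2")))
  expect_equal(overlap_report(same)$fraction_shared, 1)

  disj <- list(a = prof("f1"), b = prof("f2"))
  r <- overlap_report(disj)
  expect_equal(r$fraction_shared, 0)
  expect_equal(sum(r$region_counts), 2L)
  expect_setequal(names(r$region_counts), c("a", "b"))

  # 3 species, regions enumerated by brute force over all 2^3 - 1 subsets
  sets <- list(a = c("f1", "f2", "f3", "f5"), b = c("f1", "f3", "f4"),
               c = c("f1", "f2", "f4", "f6"))
  r3 <- overlap_report(lapply(sets, prof))
  all_f <- sort(unique(unlist(sets)))
  want <- table(vapply(all_f, function(f)
    paste(names(sets)[vapply(sets, function(s) f %in% s, logical(1))],
          collapse = "+"), character(1)))
  expect_equal(r3$region_counts[names(want)],
               stats::setNames(as.integer(want), names(want)))
  expect_equal(sum(r3$region_counts), length(all_f))
  expect_equal(r3$shared_families, "f1")
  # hit shares: each species has equal hits per family
  expect_equal(unname(r3$hit_share_shared["a"]), 1 / 4)
})

test_that("group contrast flags only patterns shared by >= 2 species", {
  prof <- function(fams, expr) data.frame(
    family = fams, n_hits = 1L, relative_expression = expr,
    stringsAsFactors = FALSE)
  profiles <- list(
    m1 = prof(c("famX", "famY", "famZ"), c(10, 5, 1)),
    m2 = prof(c("famX", "famY", "famZ"), c(12, 6, 2)),
    f1 = prof(c("famY", "famW"), c(5.5, 3)),
    f2 = prof(c("famY"), c(5.2)))
  groups <- c(m1 = "marine", m2 = "marine", f1 = "fresh", f2 = "fresh")
  ct <- group_contrast(profiles, groups)

  expect_match(ct$flag[ct$family == "famX"], "marine-specific")
  expect_match(ct$flag[ct$family == "famZ"], "marine-specific")
  expect_equal(ct$flag[ct$family == "famW"], "")   # single species: not flagged
  # famY present everywhere: marine values 5 and 6 straddle fresh max 5.5
  expect_equal(ct$flag[ct$family == "famY"], "")
  expect_equal(ct[ct$family == "famX", "mean_marine"], 11)

  # higher-in flag requires two group members above the other group's max
  profiles$m1$relative_expression[2] <- 9
  profiles$m2$relative_expression[2] <- 8
  ct2 <- group_contrast(profiles, groups)
  expect_match(ct2$flag[ct2$family == "famY"], "higher-in-marine")

  expect_warning(
    group_contrast(profiles[c("m1", "m2", "f1")],
                   groups[c("m1", "m2", "f1")]),
    "fewer than two species")
})

test_that("randomised group contrast agrees with direct rule re-evaluation", {
  set.seed(77)
  species <- c("a1", "a2", "a3", "b1", "b2")
  groups <- c(a1 = "g1", a2 = "g1", a3 = "g1", b1 = "g2", b2 = "g2")
  fams <- sprintf("fam%02d", 1:12)
  profiles <- lapply(stats::setNames(species, species), function(sp) {
    f <- fams[stats::runif(12) < 0.6]
    data.frame(family = f, n_hits = 1L,
               relative_expression = round(stats::rlnorm(length(f), 1), 3),
               stringsAsFactors = FALSE)
  })
  ct <- group_contrast(profiles, groups)
  expr_of <- function(sp, fam) {
    p <- profiles[[sp]]
    if (fam %in% p$family) p$relative_expression[p$family == fam] else NA_real_
  }
  for (fam in ct$family) {
    v <- vapply(species, expr_of, numeric(1), fam = fam)
    want <- character(0)
    for (g in c("g1", "g2")) {
      og <- setdiff(c("g1", "g2"), g)
      gv <- v[groups[species] == g]; ov <- v[groups[species] == og]
      if (sum(!is.na(gv)) >= 2 && sum(!is.na(ov)) == 0)
        want <- c(want, paste0(g, "-specific"))
      if (sum(!is.na(gv)) >= 2 && sum(!is.na(ov)) >= 1) {
        if (sum(gv > max(ov, na.rm = TRUE), na.rm = TRUE) >= 2)
          want <- c(want, paste0("higher-in-", g))
        if (sum(gv < min(ov, na.rm = TRUE), na.rm = TRUE) >= 2)
          want <- c(want, paste0("lower-in-", g))
      }
    }
    expect_equal(ct$flag[ct$family == fam], paste(want, collapse = ","))
  }
})
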