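test_that("structural validation flags exactly the three rule families", {
  expect_identical(nrow(validate_findings(rep(".", 16))), 0L)

  # unanchored pontic (R1)
  v <- validate_findings(chart_at(`5` = "b"))
  expect_identical(v$rule_id, "R1")
  # pontic at a jaw end can never be flanked on both sides
  v <- validate_findings(chart_at(`1` = "b", `2` = "k"))
  expect_identical(v$rule_id, "R1")
  # properly anchored bridges are fine
  expect_identical(nrow(validate_findings(
    chart_at(`4` = "k", `5` = "b", `6` = "k"))), 0L)
  expect_identical(nrow(validate_findings(
    chart_at(`4` = "kw", `5` = "bw", `6` = "bw", `7` = "kw"))), 0L)

  # mixed sufficiency within one FDP (R2)
  v <- validate_findings(chart_at(`4` = "k", `5` = "bw", `6` = "k"))
  expect_true("R2" %in% v$rule_id)
  # adjacent standalone crowns of mixed sufficiency carry no pontic: fine
  expect_identical(nrow(validate_findings(chart_at(`4` = "k", `5` = "kw"))), 0L)

  # mixed RDP sufficiency (R3)
  v <- validate_findings(chart_at(`3` = "e", `12` = "ew"))
  expect_identical(v$rule_id, "R3")
  expect_identical(nrow(validate_findings(chart_at(`3` = "e", `12` = "e"))), 0L)
})

test_that("gap segments carry boundedness and wisdom annotations", {
  expect_identical(nrow(find_gaps(rep(".", 16))), 0L)

  g <- find_gaps(chart_at(`8` = "f"))
  expect_identical(g$start, 8L)
  expect_identical(g$end, 8L)
  expect_true(g$bounded_left && g$bounded_right)
  expect_false(g$wisdom_only)

  g <- find_gaps(chart_at(`1` = "f", `16` = "f"))
  expect_identical(nrow(g), 2L)
  expect_true(all(g$wisdom_only))

  # a neighbour that cannot be crowned does not bound the gap
  g <- find_gaps(chart_at(`4` = "e", `5` = "x"))
  expect_false(g$bounded_left)
  expect_true(g$bounded_right)
})

test_that("replacement counting excludes wisdom teeth", {
  expect_identical(count_replacement_needs(rep(".", 16)), 0L)
  expect_identical(count_replacement_needs(chart_at(`1` = "f")), 0L)
  expect_identical(count_replacement_needs(
    chart_at(`5` = "f", `6` = "f", `9` = "x", `10` = "x")), 4L)
  expect_identical(count_replacement_needs(
    chart_at(`1` = "f", `16` = "x", `8` = "f")), 1L)
})

test_that("the removable-denture pathway fires for its three reasons", {
  expect_false(requires_rdp(rep(".", 16)))

  r <- requires_rdp(chart_at(`5` = "f", `6` = "f", `9` = "x", `10` = "x"))
  expect_true(r)
  expect_true("four_or_more" %in% attr(r, "reasons"))

  # missing tooth next to a missing wisdom tooth: no left abutment exists
  r <- requires_rdp(chart_at(`1` = "f", `2` = "f"))
  expect_true(r)
  expect_identical(attr(r, "reasons"), "unbounded_gap")

  r <- requires_rdp(chart_at(`3` = "ew", `4` = "ew"))
  expect_true(r)
  expect_identical(attr(r, "reasons"), "rdp_renewal")

  # three bounded gaps stay on the bridge pathway
  expect_false(requires_rdp(chart_at(`5` = "f", `8` = "f", `11` = "x")))
})

test_that("plan_case reproduces the hand-derived reference plans", {
  expect_identical(as.character(plan_case(rep(".", 16))), rep("-", 16))

  # single bounded gap: pontic with abutment crowns
  pl <- plan_case(chart_at(`8` = "f"))
  expect_identical(as.character(pl),
                   replace(rep("-", 16), 7:9, c("K", "B", "K")))

  # four missing teeth: removable denture
  pl <- plan_case(chart_at(`5` = "f", `6` = "f", `7` = "f", `8` = "f"))
  expect_identical(as.character(pl), replace(rep("-", 16), 5:8, "E"))

  # insufficient denture forces renewal and routes the new gap into it
  pl <- plan_case(chart_at(`3` = "ew", `4` = "ew", `10` = "f"))
  expect_identical(as.character(pl), replace(rep("-", 16), c(3, 4, 10), "E"))

  # renewals independent of gaps
  expect_identical(as.character(plan_case(chart_at(`6` = "kw"))),
                   replace(rep("-", 16), 6, "K"))
  pl <- plan_case(chart_at(`4` = "kw", `5` = "bw", `6` = "kw"))
  expect_identical(as.character(pl),
                   replace(rep("-", 16), 4:6, c("K", "B", "K")))
  expect_identical(as.character(plan_case(chart_at(`9` = "ww"))),
                   replace(rep("-", 16), 9, "K"))

  # missing wisdom teeth are never treated
  expect_identical(as.character(plan_case(chart_at(`1` = "f", `16` = "x"))),
                   rep("-", 16))

  # sufficient denture with no replacement need stays untreated
  expect_identical(as.character(plan_case(chart_at(`3` = "e", `4` = "e"))),
                   rep("-", 16))
  # ... but is renewed when new replacements force a denture
  pl <- plan_case(chart_at(`3` = "e", `4` = "e", `6` = "f", `7` = "f",
                           `9` = "f", `11` = "f"))
  expect_identical(as.character(pl),
                   replace(rep("-", 16), c(3, 4, 6, 7, 9, 11), "E"))

  expect_error(plan_case(chart_at(`5` = "b")), "invalid findings chart")
})

test_that("plan_contains_fdp detects bridge units only", {
  expect_false(plan_contains_fdp(rep("-", 16)))
  expect_true(plan_contains_fdp(replace(rep("-", 16), 7:9, c("K", "B", "K"))))
  expect_false(plan_contains_fdp(rep("E", 16)))
})

test_that("plans satisfy the structural invariants on random valid charts", {
  set.seed(42)
  cfg <- generator_config(n_total = 10, n_test = 5)  # only for sampling
  for (i in 1:300) {
    ch <- as.character(sample_findings(cfg, force_fdp = i %% 2 == 0))
    expect_identical(nrow(validate_findings(ch)), 0L)
    pl <- as.character(plan_case(ch))
    expect_identical(length(pl), 16L)
    expect_true(all(pl %in% c("-", "K", "B", "E")))

    # no cantilevers: every maximal B run flanked by K on both sides
    r <- rle(pl == "B")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      expect_true(starts[j] > 1 && pl[starts[j] - 1] == "K")
      expect_true(ends[j] < 16 && pl[ends[j] + 1] == "K")
    }

    # wisdom positions never enter the denture
    expect_true(all(pl[c(1, 16)] != "E"))

    # E implies one of the three denture reasons
    if (any(pl == "E")) {
      rdp <- requires_rdp(ch)
      expect_true(rdp)
      expect_true(length(attr(rdp, "reasons")) >= 1)
    }

    # all-or-none renewal of an insufficient denture
    if (any(ch == "ew"))
      expect_true(all(pl[ch == "ew"] == "E"))

    # determinism
    expect_identical(as.character(plan_case(ch)), pl)
  }
})
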