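test_that("hull membership handles interior, exterior and boundary points", {
  t <- unit_square_table(rbind(c(2, 2), c(0.5, 0.5), c(1.0, 0.5)))
  hp <- presence_hull(t)
  expect_equal(nrow(hp$hull), 4)
  cand_ids <- t$id[!t$surveyed]
  expect_true(cand_ids[1] %in% hp$outside_ids)   # (2,2)
  expect_true(cand_ids[2] %in% hp$inside_ids)    # interior
  expect_true(cand_ids[3] %in% hp$inside_ids)    # on an edge
  # every presence is inside its own hull
  pres <- t[t$surveyed & t$presence == 1, ]
  expect_true(all(points_in_hull(cbind(pres$x, pres$y), hp$hull)))
})

test_that("degenerate presence configurations fail explicitly", {
  t <- unit_square_table(cbind(2, 2))
  t$presence[t$surveyed] <- c(1L, 1L, 0L, 0L, 0L, 0L)
  expect_error(presence_hull(t), "degenerate")
  t2 <- unit_square_table(cbind(2, 2))
  t2$x[1:4] <- c(0, 1, 2, 3); t2$y[1:4] <- c(0, 1, 2, 3)  # collinear
  expect_error(presence_hull(t2), "collinear|degenerate")
})

test_that("hull partition agrees exactly with a ray-casting oracle", {
  l <- generate_landscape(simulation_config(seed = 3))
  hp <- presence_hull(l)
  set.seed(21)
  pts <- cbind(runif(1000, 0, 600), runif(1000, 0, 560))
  expect_identical(unname(points_in_hull(pts, hp$hull)),
                   unname(ray_cast_inside(pts, hp$hull)))
  # the unsurveyed partition itself matches the oracle
  cand <- l[!l$surveyed, ]
  oracle_in <- ray_cast_inside(cbind(cand$x, cand$y), hp$hull)
  on_edge <- points_in_hull(cbind(cand$x, cand$y), hp$hull) != oracle_in
  # disagreement is only possible for points exactly on the boundary
  expect_identical(cand$id[points_in_hull(cbind(cand$x, cand$y), hp$hull)][!on_edge],
                   cand$id[oracle_in][!on_edge])
})

test_that("distant and proximal cells partition the unsurveyed pool", {
  l <- generate_landscape(simulation_config(seed = 5))
  hp <- presence_hull(l)
  pool <- l$id[!l$surveyed]
  expect_setequal(c(hp$inside_ids, hp$outside_ids), pool)
  expect_length(intersect(hp$inside_ids, hp$outside_ids), 0)
})

test_that("pseudoabsence draws respect strategy, count and determinism", {
  l <- generate_landscape(simulation_config(seed = 1))
  hp <- presence_hull(l)

  set.seed(2)
  po_d <- draw_pseudoabsences(l, "distant")
  expect_equal(sum(po_d$label == 1), 184)
  expect_equal(sum(po_d$label == 0), 284)
  drawn <- po_d$ids[po_d$role == "pseudoabsence"]
  expect_true(all(drawn %in% hp$outside_ids))
  # independent geometric check on the drawn coordinates
  dc <- po_d$coords[po_d$role == "pseudoabsence", ]
  expect_true(all(!ray_cast_inside(dc, hp$hull)))
  # true absences never appear
  expect_length(intersect(po_d$ids, l$id[l$surveyed & l$presence == 0]), 0)

  set.seed(2)
  po_d2 <- draw_pseudoabsences(l, "distant")
  expect_identical(po_d$ids, po_d2$ids)

  # drawing the whole pool returns each unsurveyed lake exactly once
  po_all <- draw_pseudoabsences(l, "random", n_pseudo = sum(!l$surveyed))
  expect_setequal(po_all$ids[po_all$role == "pseudoabsence"],
                  l$id[!l$surveyed])

  expect_error(draw_pseudoabsences(l, "distant", n_pseudo = 10000),
               "candidate")
})

test_that("build_dataset assembles the five kinds with the study's sizes", {
  l <- generate_landscape(simulation_config(seed = 1))
  pa <- build_dataset(l, "PA")
  expect_equal(length(pa$ids), 468)
  expect_setequal(unique(pa$label), c(0, 1))

  ab <- build_dataset(l, "ABUNDANCE")
  expect_equal(length(ab$ids), 468)
  expect_true(all(ab$label[ab$role == "absence"] == 0))
  expect_true(all(ab$label[ab$role == "presence"] > 0))

  set.seed(3)
  for (k in c("PO_random", "PO_distant", "PO_proximal")) {
    po <- build_dataset(l, k)
    expect_equal(sum(po$label == 1), 184)
    expect_equal(sum(po$label == 0), 284)
    expect_false(anyDuplicated(po$ids) > 0)
  }
})

test_that("lakes with incomplete covariates are dropped and logged", {
  l <- generate_landscape(small_config(seed = 11))
  l$secchi_depth[which(l$surveyed)[1]] <- NA
  expect_message(ds <- build_dataset(l, "PA"), "dropped 1 lake")
  expect_equal(length(ds$ids), sum(l$surveyed) - 1)
})

test_that("hull exports as a closed WKT polygon", {
  t <- unit_square_table(cbind(2, 2))
  wkt <- hull_to_wkt(presence_hull(t))
  expect_match(wkt, "^POLYGON \\(\\(")
  coords <- strsplit(sub("\\)\\)$", "", sub("^POLYGON \\(\\(", "", wkt)),
                     ", ")[[1]]
  expect_identical(coords[1], coords[length(coords)])  # closed ring
  expect_equal(length(coords), 5)
})

test_that("response datasets round-trip through CSV", {
  l <- generate_landscape(small_config(seed = 11))
  set.seed(1)
  ds <- build_dataset(l, "PO_random")
  f <- withr::local_tempfile(fileext = ".csv")
  write_response_dataset(ds, f)
  back <- read_response_dataset(f, "PO_random")
  expect_equal(back$label, ds$label)
  expect_equal(back$role, ds$role)
  expect_equal(back$features$gdd_wtr_10c, ds$features$gdd_wtr_10c,
               tolerance = 1e-12)
})
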