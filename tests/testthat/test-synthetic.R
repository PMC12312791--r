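test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_pos = 20, n_neg = 20, seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$embeddings, d2$embeddings)
  expect_identical(lapply(d1$records, unclass), lapply(d2$records, unclass))

  dir1 <- tempfile(); dir2 <- tempfile()
  write_dataset(d1, dir1)
  write_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("datasets round-trip through their on-disk formats", {
  d <- generate_dataset(sim_config(n_pos = 15, n_neg = 15, seed = 78))
  dir <- tempfile()
  write_dataset(d, dir)
  back <- read_dataset(dir)
  expect_equal(vapply(back$records, `[[`, "", "id"),
               vapply(d$records, `[[`, "", "id"))
  expect_equal(vapply(back$records, `[[`, 1L, "label"),
               vapply(d$records, `[[`, 1L, "label"))
  expect_equal(lapply(back$records, function(r) sort(r$go_terms)),
               lapply(d$records, function(r) sort(r$go_terms)))
  expect_equal(unname(back$embeddings), unname(d$embeddings),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("class signal scales with the injected effect size", {
  fast <- dnn_config(max_epochs = 20L, seed = 1L)
  auc_at <- function(delta, seed) {
    d <- generate_dataset(sim_config(n_pos = 100, n_neg = 100,
                                     effect_size = delta,
                                     go_prob_pos = 0.3, go_prob_neg = 0.3,
                                     seed = seed))
    res <- cross_validate(d, folds = 3, runs = 1, k = 20, dnn = fast,
                          seed = seed)
    res$summary$mean[res$summary$metric == "auc"]
  }
  a0 <- mean(vapply(80:81, function(s) auc_at(0, s), numeric(1)))
  a3 <- mean(vapply(80:81, function(s) auc_at(3, s), numeric(1)))
  expect_gt(a3, a0 + 0.2)
  expect_lt(a0, 0.65)
})

test_that("enriched GO terms alone carry recoverable class signal", {
  d <- generate_dataset(sim_config(n_pos = 150, n_neg = 150, effect_size = 0,
                                   go_prob_pos = 0.8, go_prob_neg = 0.2,
                                   seed = 82))
  res <- cross_validate(d, folds = 3, runs = 1, k = 30,
                        dnn = dnn_config(seed = 2L), seed = 5)
  expect_gte(res$summary$mean[res$summary$metric == "auc"], 0.85)
  # the GO blocks, not the unshifted embedding block, carry the separability
  jm <- jm_report(d)
  expect_true(all(jm[c("go_MF", "go_CC", "go_BP")] > jm["embedding"]))
  expect_gt(max(jm[c("go_MF", "go_CC", "go_BP")]), 0.5)
})

test_that("JM separability tracks the generator's knobs", {
  jm_emb <- function(delta) {
    d <- generate_dataset(sim_config(n_pos = 60, n_neg = 60,
                                     effect_size = delta,
                                     go_prob_pos = 0.3, go_prob_neg = 0.3,
                                     seed = 83))
    jm_report(d)["embedding"]
  }
  expect_gt(jm_emb(3), jm_emb(1))
  expect_gt(jm_emb(1), jm_emb(0))
})

test_that("toy CA traces honour backbone spacing and self-avoidance", {
  rec <- generate_toy_structure(60, seed = 9)
  steps <- sqrt(rowSums(diff(rec$ca_coords)^2))
  expect_equal(steps, rep(3.8, 59), tolerance = 1e-9)
  d <- as.matrix(dist(rec$ca_coords))
  noncons <- abs(row(d) - col(d)) > 1
  expect_gte(min(d[noncons]), 4.0)
})

test_that("toy structures round-trip as PDB files", {
  path <- tempfile(fileext = ".pdb")
  rec <- generate_toy_structure(25, seed = 10, path = path)
  back <- read_pdb_monomer(path)
  expect_equal(back$n_residues, 25L)
  expect_equal(unname(back$ca_coords), unname(round(rec$ca_coords, 3)),
               tolerance = 1e-8)
  single <- generate_toy_structure(1, seed = 11)
  expect_equal(unclass(contact_map(single$ca_coords))[1, 1], 1L)
})
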