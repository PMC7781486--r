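test_that("enumeration yields 256 designs, 255 without the all-STOP circuit", {
  full <- blade_circuits(include_trivial = TRUE)
  expect_equal(nrow(full), 256)
  expect_equal(nrow(blade_circuits()), 255)

  # duplicate-free: every 4-gene assignment appears exactly once
  key <- paste(full$gene_Z00, full$gene_Z10, full$gene_Z01, full$gene_Z11)
  expect_equal(length(unique(key)), 256)

  # the excluded design is exactly the all-STOP one
  dropped <- dplyr::anti_join(full, blade_circuits(), by = "circuit_id")
  expect_equal(nrow(dropped), 1)
  expect_true(all(unlist(dropped[paste0("gene_", c("Z00", "Z10", "Z01", "Z11"))]) == "STOP"))

  # enumeration is deterministic
  expect_identical(full, blade_circuits(include_trivial = TRUE))
})

test_that("ideal vectors reproduce the printed truth tables bit-exactly", {
  # the ordering convention (address-major, (GFP, mCherry) within address)
  # is derived from the two printed design/vector pairs and must match them
  v3 <- ideal_vector(genes_train1)
  expect_equal(as.numeric(v3), c(100, 100, 100, 0, 0, 0, 100, 0))
  expect_equal(attr(v3, "n_fluorescent"), 4L)

  v4 <- ideal_vector(genes_train2)
  expect_equal(as.numeric(v4), c(100, 100, 0, 0, 0, 100, 0, 100))
  expect_equal(attr(v4, "n_fluorescent"), 4L)

  v2 <- ideal_vector(c("STOP", "STOP", "STOP", "mCherry"))
  expect_equal(as.numeric(v2), c(0, 0, 0, 0, 0, 0, 0, 100))
  expect_equal(attr(v2, "n_fluorescent"), 1L)

  v0 <- ideal_vector(rep("STOP", 4))
  expect_equal(as.numeric(v0), rep(0, 8))
  expect_equal(attr(v0, "n_fluorescent"), 0L)
})

test_that("n_fluorescent equals the number of expressed reporters over addresses", {
  genes <- blade_genes()
  circuits <- blade_circuits(include_trivial = TRUE)
  for (i in sample.int(nrow(circuits), 40)) {
    g <- unlist(circuits[i, paste0("gene_", c("Z00", "Z10", "Z01", "Z11"))])
    idx <- match(g, genes$gene)
    expect_equal(circuits$n_fluorescent[i],
                 sum(genes$expresses_gfp[idx]) + sum(genes$expresses_mcherry[idx]))
    expect_true(all(unlist(circuits[i, paste0("ideal_v", 1:8)]) %in% c(0, 100)))
  }
})

test_that("invalid designs are rejected", {
  expect_error(ideal_vector(c("GFP", "GFP", "GFP")), "4 genes")
  expect_error(ideal_vector(c("GFP", "GFP", "GFP", "RFP")), "unknown gene")
})

test_that("circuit tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  circuits <- blade_circuits()
  write_circuit_table(circuits, path)
  back <- read_circuit_table(path)
  expect_equal(as.data.frame(back), as.data.frame(circuits))
})
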