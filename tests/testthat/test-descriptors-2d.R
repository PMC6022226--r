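# Connectivity (chi) indices and atomic-composition information content,
# checked against hand enumeration and a brute-force subgraph oracle.

test_that("chi indices reproduce hand-enumerated values", {
  expect_equal(chi_cluster_3(parse_structure("CC")), 0)
  expect_equal(chi_cluster_3(parse_structure("CC(C)C")),
               1 / sqrt(3), tolerance = 1e-10)   # 0.5774
  expect_equal(chi_cluster_3(parse_structure("CC(C)(C)C")), 2.0,
               tolerance = 1e-10)                # neopentane
  expect_equal(chi_index(parse_structure("CC"), 0), 2.0)
  expect_equal(chi_index(parse_structure("CCCC"), 1),
               1 / sqrt(2) + 1 / 2 + 1 / sqrt(2), tolerance = 1e-10) # 1.9142
  expect_equal(round(chi_index(parse_structure("CCCC"), 1), 4), 1.9142)
})

test_that("unsupported order/kind combinations error", {
  m <- parse_structure("CCC")
  expect_error(chi_index(m, 2, "cluster"), "cluster")
  expect_error(chi_index(m, 4), "unsupported")
})

test_that("chi equals the brute-force subgraph oracle on fixtures and random graphs", {
  for (mol in lapply(cached_fixtures()[c("4a", "8b", "11c", "15c")],
                     `[[`, "molecule"))
    for (ord in 0:3) {
      expect_equal(chi_index(mol, ord, "path"), brute_chi(mol, ord, "path"),
                   tolerance = 1e-12, label = paste(mol$id, ord, "path"))
      if (ord == 3)
        expect_equal(chi_index(mol, 3, "cluster"),
                     brute_chi(mol, 3, "cluster"),
                     tolerance = 1e-12, label = paste(mol$id, "cluster"))
    }
  set.seed(42)
  for (k in 1:50) {
    mol <- random_graph_mol(sample(4:12, 1), extra = sample(0:3, 1))
    for (ord in 0:3)
      expect_equal(chi_index(mol, ord, "path"), brute_chi(mol, ord, "path"),
                   tolerance = 1e-12)
    expect_equal(chi_index(mol, 3, "cluster"), brute_chi(mol, 3, "cluster"),
                 tolerance = 1e-12)
  }
})

test_that("chi and IAC are invariant to atom reordering", {
  mol <- cached_fixtures()[["8d"]]$molecule
  set.seed(7)
  for (k in 1:5) {
    perm <- sample(nrow(mol$atoms))
    inv <- order(perm)
    pm <- new_molecule(mol$id,
                       mol$atoms[perm, c("element", "formal_charge",
                                         "n_implicit_h")],
                       data.frame(i = inv[mol$bonds$i], j = inv[mol$bonds$j],
                                  order = mol$bonds$order))
    expect_equal(chi_index(pm, 3, "path"), chi_index(mol, 3, "path"),
                 tolerance = 1e-12)
    expect_equal(chi_cluster_3(pm), chi_cluster_3(mol), tolerance = 1e-12)
    expect_equal(iac_mean(pm), iac_mean(mol), tolerance = 1e-12)
  }
})

test_that("IAC is the composition entropy in bits", {
  expect_equal(iac_mean(parse_structure("C")),
               -(0.2 * log2(0.2) + 0.8 * log2(0.8)), tolerance = 1e-10)
  expect_equal(round(iac_mean(parse_structure("C")), 4), 0.7219)
  expect_equal(iac_mean(parse_structure("[H][H]")), 0)

  # definitional identity and the alternative entropy route on fixtures
  for (f in cached_fixtures()[c("4a", "11b")]) {
    mol <- f$molecule
    n <- nrow(mol$atoms) + sum(mol$atoms$n_implicit_h)
    expect_equal(iac_total(mol), n * iac_mean(mol), tolerance = 1e-9)
    el <- c(mol$atoms$element, rep("H", sum(mol$atoms$n_implicit_h)))
    p <- as.numeric(table(el)) / n
    expect_equal(iac_mean(mol), -sum(p * log2(p)), tolerance = 1e-12)
  }

  # equal counts maximize the per-atom entropy for a fixed element set
  even <- graph_mol(cbind(1:3, 2:4), elements = c("C", "N", "O", "S"))
  uneven <- graph_mol(cbind(1:3, 2:4), elements = c("C", "C", "C", "S"))
  expect_gt(iac_mean(even), iac_mean(uneven))
  expect_equal(iac_mean(even), 2)  # log2(4), no hydrogens on bare graph
})

test_that("hydrogen handling flag changes the composition", {
  m <- parse_structure("CO")
  expect_gt(iac_mean(m, include_hydrogens = TRUE), 0)
  expect_equal(iac_mean(m, include_hydrogens = FALSE), 1)  # C,O equal split
})
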