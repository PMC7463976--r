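elec <- electrolyte_params()

test_that("baseline domain meshes cleanly with all boundary groups tagged", {
  num <- resolution_profile("coarse")
  dom <- build_domain(sim_geometry(y_p = bp_to_m(-300)))
  m <- generate_mesh(dom, num, elec)
  tags <- sort(unique(m$be_tag))
  expect_setequal(names(poreflow:::PF_TAGS)[match(tags, poreflow:::PF_TAGS)],
                  c("AXIS", "TOP_WALL", "BOTTOM_WALL", "SIDE_BOUNDARY",
                    "MEMBRANE_WALL", "PARTICLE_SURFACE"))
  q <- mesh_quality(m)
  expect_gt(q$min_angle, 15)
  expect_identical(q$bl_violations, 0L)
  expect_gte(q$n_tri, 2000)
  # meshed area equals the analytic fluid area
  area <- sum(poreflow:::.tri_area(m$p, m$t))
  expect_lt(abs(area - poreflow:::.domain_area(dom)) /
              poreflow:::.domain_area(dom), 0.005)
  # the particle sits fully inside the lower reservoir
  expect_lt(dom$z_hi, -dom$hh)
})

test_that("default resolution reaches production element counts mid-pore", {
  num <- resolution_profile("default")
  dom <- build_domain(sim_geometry(y_p = 0))
  m <- generate_mesh(dom, num, elec)
  expect_gte(nrow(m$t), 20000)
  q <- mesh_quality(m)
  expect_gt(q$min_angle, 15)
  expect_identical(q$bl_violations, 0L)
})

test_that("domain is symmetric under axial reflection at y_p = 0", {
  num <- resolution_profile("coarse")
  dom <- build_domain(sim_geometry(y_p = 0))
  m <- generate_mesh(dom, num, elec)
  # classifying the mirrored boundary-edge midpoints reproduces the tags
  m2 <- m
  m2$p[, 2] <- -m2$p[, 2]
  tags_flipped <- poreflow:::.classify_edges(m2$be, m2$p, dom)
  flip <- function(tg) {
    tg[tg == poreflow:::PF_TAGS[["TOP_WALL"]]] <- -1L
    tg[tg == poreflow:::PF_TAGS[["BOTTOM_WALL"]]] <- poreflow:::PF_TAGS[["TOP_WALL"]]
    tg[tg == -1L] <- poreflow:::PF_TAGS[["BOTTOM_WALL"]]
    tg
  }
  expect_identical(unname(tags_flipped), unname(flip(m$be_tag)))
})

test_that("boundary-layer refinement responds to the size fraction", {
  dom <- build_domain(sim_geometry(y_p = bp_to_m(-300)))
  count_bl_edges <- function(bl_frac) {
    num <- numerics_params(bl_frac = bl_frac, h_bulk = 14e-9)
    m <- generate_mesh(dom, num, elec)
    ed <- poreflow:::.mesh_edges(m$t)
    band <- 2 * m$lambda_nm
    d1 <- abs(poreflow:::.d_particle(m$p[ed[, 1], 1], m$p[ed[, 1], 2], dom))
    d2 <- abs(poreflow:::.d_particle(m$p[ed[, 2], 1], m$p[ed[, 2], 2], dom))
    sum(d1 < band & d2 < band)
  }
  n_coarse <- count_bl_edges(0.6)
  n_fine <- count_bl_edges(0.3)
  # halving the target edge size should roughly double in-band edge counts
  # per direction; in 2-D the count grows faster still
  expect_gt(n_fine / n_coarse, 1.6)
})

test_that("geometry guards reject impossible configurations", {
  expect_error(build_domain(sim_geometry(y_p = bp_to_m(550))), "reservoir")
  # clearance below mesh resolution
  expect_error(build_domain(sim_geometry(b = 2.2e-9, a = 1e-9)), "clearance")
})

test_that("mesh_quality flags a degenerate hand-built triangle", {
  m <- structure(list(
    p = rbind(c(0, 0), c(1, 0), c(0.5, 0.044)), # ~5 degree apex angles
    t = matrix(c(1, 2, 3), 1), be = rbind(c(1, 2), c(2, 3), c(3, 1)),
    be_tag = rep(poreflow:::PF_TAGS[["SIDE_BOUNDARY"]], 3),
    node_tag = rep(1L, 3), lambda_nm = NA_real_, bl_h = NA_real_,
    dom = NULL, mode = "planar2d"), class = "pf_mesh")
  q <- mesh_quality(m)
  expect_lt(q$min_angle, 10)
})

test_that("mesh export round-trips through VTU and writes valid MSH", {
  num <- resolution_profile("coarse")
  dom <- build_domain(sim_geometry(y_p = 0))
  m <- generate_mesh(dom, num, elec)
  vtu <- tempfile(fileext = ".vtu")
  export_fields_vtu(m, vtu)
  back <- read_fields_vtu(vtu)
  expect_equal(back$p, unname(m$p), tolerance = 1e-12)
  expect_identical(back$t, m$t)
  msh <- tempfile(fileext = ".msh")
  export_mesh_msh(m, msh)
  lines <- readLines(msh)
  expect_identical(lines[1], "$MeshFormat")
  expect_identical(sum(lines == "$EndElements"), 1L)
  n_declared <- as.integer(lines[which(lines == "$Elements") + 1])
  expect_identical(n_declared, nrow(m$t) + nrow(m$be))
})
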