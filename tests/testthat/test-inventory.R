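test_that("inventory loading types records and counts coercions", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "inv.csv")
  writeLines(c(
    "reservoir_id,name,state,latitude,longitude,year_completed,storage_volume_m3,max_discharge_m3s,surface_area_ha",
    "R1,Lake One,TX,31.5,-95.2,1950,1000000,12.5,120",
    "R2,Lake Two,OK,35.1,-97.8,1962,n/a,3.2,45",
    "R3,Lake Three,AR,34.0,-92.5,1971,500000,,60"), path)
  inv <- load_inventory(path)
  expect_equal(nrow(inv), 3)
  expect_true(is.na(inv$storage_volume_m3[2]))
  expect_equal(attr(inv, "coercion_warnings")[["storage_volume_m3"]], 1L)

  expect_error(load_inventory(file.path(dir, "missing.csv")), "I/O error")
  writeLines(c("dam_no,name", "1,A"), file.path(dir, "noid.csv"))
  expect_error(load_inventory(file.path(dir, "noid.csv")), "schema error")

  # column mapping renames file columns onto the canonical layout
  writeLines(c("DAM_ID,DAM_NAME,ST,VOL", "d1,Big Dam,TX,5000"),
             file.path(dir, "mapped.csv"))
  inv2 <- load_inventory(file.path(dir, "mapped.csv"),
                         column_map = c(reservoir_id = "DAM_ID",
                                        name = "DAM_NAME", state = "ST",
                                        storage_volume_m3 = "VOL"))
  expect_equal(inv2$reservoir_id, "d1")
  expect_equal(inv2$storage_volume_m3, 5000)
})

test_that("cleaning applies the three rules with a full accounting", {
  toy <- tibble::tibble(
    reservoir_id = paste0("R", 1:6),
    name = c("Lake Alpha", "Lake Alpha", "Lake Beta", "Lake Superior",
             "Lake Gamma", "Lake Delta"),
    state = c("TX", "TX", "OK", "MN", "AR", "LA"),
    latitude = NA_real_, longitude = NA_real_,
    year_completed = 1950L,
    storage_volume_m3 = c(100, 500, 200, 1e9, 300, 400),
    max_discharge_m3s = 1, surface_area_ha = c(10, 50, 20, 1e6, 30, 40),
    natural_lake = FALSE)
  out <- clean_inventory(toy)
  expect_equal(nrow(out$records), 4)
  expect_equal(out$report$duplicates, 1L)
  expect_equal(out$report$natural_lakes, 1L)
  # the max-storage dam is the one kept for the duplicated reservoir
  expect_true("R2" %in% out$records$reservoir_id)
  expect_false("R1" %in% out$records$reservoir_id)

  # empty input: empty output, zero-count report
  out0 <- clean_inventory(toy[0, , drop = FALSE])
  expect_equal(nrow(out0$records), 0)
  expect_equal(out0$report$duplicates, 0L)

  # rows with neither area nor volume are dropped (no basis for area)
  toy2 <- toy[3, , drop = FALSE]
  toy2$surface_area_ha <- NA_real_
  toy2$storage_volume_m3 <- NA_real_
  expect_equal(clean_inventory(toy2)$report$no_area_basis, 1L)
})

test_that("cleaning is idempotent and row counts partition", {
  cfg <- simulation_config(seed = 9, n_reservoirs = 400)
  inv <- simulate_inventory(cfg)
  once <- clean_inventory(inv)
  twice <- clean_inventory(once$records)
  expect_equal(twice$records, once$records)
  expect_equal(twice$report$duplicates + twice$report$natural_lakes +
                 twice$report$no_area_basis, 0L)
  rep <- once$report
  expect_equal(rep$n_out + rep$duplicates + rep$natural_lakes +
                 rep$no_area_basis, rep$n_in)
})

test_that("area approximation recovers a noiseless power law and never touches observed areas", {
  base <- tibble::tibble(
    reservoir_id = paste0("R", 1:13),
    name = paste("Res", 1:13), state = "TX",
    latitude = NA_real_, longitude = NA_real_, year_completed = 1950L,
    storage_volume_m3 = c(10^seq(3, 8.5, length.out = 12), 1e6),
    max_discharge_m3s = 1,
    surface_area_ha = NA_real_, natural_lake = FALSE)
  base$surface_area_ha <- 0.1 * base$storage_volume_m3^0.8
  complete <- base
  expect_equal(approximate_missing_area(complete)$surface_area_ha,
               complete$surface_area_ha)  # identity when nothing is missing

  miss <- base
  miss$surface_area_ha[13] <- NA_real_
  out <- approximate_missing_area(miss)
  expect_equal(out$surface_area_ha[13], 0.1 * 10^(0.8 * 6),
               tolerance = 1e-6)
  expect_true(out$area_approximated[13])
  expect_equal(out$surface_area_ha[1:12], miss$surface_area_ha[1:12])

  # under 10 complete pairs: documented median-ratio fallback
  small <- miss[c(1:4, 13), , drop = FALSE]
  out2 <- approximate_missing_area(small)
  ratio <- stats::median(small$surface_area_ha[1:4] /
                           small$storage_volume_m3[1:4])
  expect_equal(out2$surface_area_ha[5], ratio * 1e6)

  none <- miss
  none$surface_area_ha <- NA_real_
  expect_error(approximate_missing_area(none), "estimation error")
})

test_that("ecoregion assignment matches an independent ray-casting oracle", {
  unit <- structure(list(labels = "E1",
                         rings = list(cbind(c(0, 1, 1, 0, 0),
                                            c(0, 0, 1, 1, 0)))),
                    class = "ecoregion_layer")
  rec <- tibble::tibble(reservoir_id = c("a", "b", "c"),
                        latitude = c(0.5, 2, NA), longitude = c(0.5, 2, NA))
  out <- assign_ecoregion(rec, unit)
  expect_equal(out$ecoregion_l2, c("E1", NA, NA))
  expect_equal(attr(out, "n_unassigned"), 2L)

  layer <- make_ecoregion_grid(4, bbox = c(0, 2, 0, 2))
  set.seed(123)
  pts <- tibble::tibble(reservoir_id = sprintf("p%03d", 1:100),
                        longitude = runif(100, -0.2, 2.2),
                        latitude = runif(100, -0.2, 2.2))
  got <- assign_ecoregion(pts, layer)$ecoregion_l2
  oracle <- vapply(seq_len(100), function(i) {
    ray_cast_label(pts$longitude[i], pts$latitude[i], layer)
  }, character(1))
  expect_equal(got, oracle)

  expect_error(assign_ecoregion(rec, structure(
    list(labels = character(), rings = list()), class = "ecoregion_layer")),
    "configuration error")
})
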