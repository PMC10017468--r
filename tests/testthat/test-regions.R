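test_that("default region map reaches exactly 10 composite regions from 28 VOIs", {
  map <- default_region_map()
  expect_equal(nrow(map), 28)
  expect_setequal(unique(map$region), region_names())
  expect_equal(length(region_names()), 10)
  # every VOI maps to exactly one region
  expect_equal(anyDuplicated(map$voi_name), 0L)
  # 5 lobes x 2 hemispheres
  expect_setequal(unique(map$lobe), lobe_names())
  expect_setequal(unique(map$hemisphere), c("left", "right"))
  # bilateral VOI counts per lobe follow the anatomical listing
  # (parietal 5, temporal 3, frontal 2 composites, cingulate 2, striatum 2)
  counts <- table(map$lobe) / 2
  expect_equal(as.vector(counts[c("frontal", "lateral_temporal", "parietal",
                                  "cingulate", "striatum")]),
               c(2, 3, 5, 2, 2))
})

test_that("region map validation rejects malformed maps", {
  map <- default_region_map()
  expect_error(validate_region_map(map[map$region != "cingulate_left", ]),
               "must reach all 10")
  bad <- map
  bad$lobe[1] <- "occipital"
  expect_error(validate_region_map(bad), "unknown lobe")
  dup <- rbind(map, map[1, ])
  expect_error(validate_region_map(dup), "duplicated")
})

test_that("regional SUVR is the volume-weighted mean over the reference", {
  map <- default_region_map()
  # two VOIs of the left cingulate: equal volumes -> plain mean / reference
  vois <- tibble::tibble(
    participant_id = "a", ligand = "FBB",
    voi_name = c(map$voi_name, "Cerebellum_Whole"),
    mean_uptake = 2.0, volume = 100
  )
  vois$mean_uptake[vois$voi_name == "Cingulum_Ant_L"] <- 2.0
  vois$mean_uptake[vois$voi_name == "Cingulum_Post_L"] <- 4.0
  prof <- aggregate_profiles(vois)
  expect_equal(prof$cingulate_left, (2 + 4) / 2 / 2.0)

  # unequal volumes (1, 3): weighted mean (2*1 + 4*3) / 4 / 2 = 1.75
  vois$volume[vois$voi_name == "Cingulum_Ant_L"] <- 1
  vois$volume[vois$voi_name == "Cingulum_Post_L"] <- 3
  prof <- aggregate_profiles(vois)
  expect_equal(prof$cingulate_left, 1.75)

  # all uptakes equal to the reference -> every SUVR exactly 1
  vois$mean_uptake <- 2.0
  prof <- aggregate_profiles(vois)
  expect_equal(unname(unlist(prof[, c(region_names(), "global_suvr")])),
               rep(1, 11))
})

test_that("aggregation is invariant to VOI order and joint rescaling", {
  vois <- synthetic_voi_table(n = 3, seed = 11)
  base <- aggregate_profiles(vois)
  shuffled <- vois[sample(nrow(vois)), ]
  expect_equal(aggregate_profiles(shuffled), base)
  scaled <- dplyr::mutate(vois, mean_uptake = mean_uptake * 7.3)
  expect_equal(aggregate_profiles(scaled), base)
})

test_that("aggregation errors name the problem", {
  vois <- synthetic_voi_table(n = 1, seed = 2)
  expect_error(aggregate_profiles(vois[vois$voi_name != "Precuneus_L", ]),
               "Precuneus_L")
  noref <- vois[vois$voi_name != "Cerebellum_Whole", ]
  expect_error(aggregate_profiles(noref), "reference VOI")
  zeroref <- vois
  zeroref$mean_uptake[zeroref$voi_name == "Cerebellum_Whole"] <- 0
  expect_error(aggregate_profiles(zeroref), "reference uptake")
  dup <- rbind(vois, vois[vois$voi_name == "Putamen_R", ])
  expect_error(aggregate_profiles(dup), "duplicated")
})

test_that("region maps round-trip through CSV and YAML", {
  map <- default_region_map()
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(map[, c("voi_name", "lobe", "hemisphere")], csv,
                   row.names = FALSE)
  expect_equal(read_region_map(csv)$voi_name, map$voi_name)

  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(
    purrr::pmap(map[, c("voi_name", "lobe", "hemisphere")], list), yml)
  expect_equal(read_region_map(yml)$region, map$region)
})

test_that("extract_voi_means matches a per-voxel loop oracle", {
  # constant field: every mean is the constant
  labs <- array(rep(c(1L, 2L, 0L), length.out = 24), dim = c(2, 3, 4))
  img <- array(3.0, dim = c(2, 3, 4))
  lt <- data.frame(label = c(1, 2), voi_name = c("A", "B"))
  out <- extract_voi_means(img, labs, lt)
  expect_equal(out$mean_uptake, c(3, 3))

  # two-voxel mean
  out2 <- extract_voi_means(array(c(2, 4), dim = c(2, 1, 1)),
                            array(c(7L, 7L), dim = c(2, 1, 1)),
                            c("7" = "X"))
  expect_equal(out2$mean_uptake, 3)
  expect_equal(out2$volume, 2)

  # random volume vs brute-force voxel loop
  set.seed(33)
  img <- array(runif(60), dim = c(3, 4, 5))
  labs <- array(sample(0:4, 60, replace = TRUE), dim = c(3, 4, 5))
  lt <- data.frame(label = 1:4, voi_name = paste0("R", 1:4))
  out <- extract_voi_means(img, labs, lt)
  sums <- counts <- numeric(4)
  for (i in 1:3) for (j in 1:4) for (k in 1:5) {
    l <- labs[i, j, k]
    if (l >= 1) {
      sums[l] <- sums[l] + img[i, j, k]
      counts[l] <- counts[l] + 1
    }
  }
  oracle <- sums[counts > 0] / counts[counts > 0]
  expect_equal(out$mean_uptake[order(out$voi_name)], oracle)
  expect_equal(out$volume[order(out$voi_name)], counts[counts > 0])

  # labels absent from the image are omitted; shape mismatch errors
  lt2 <- rbind(lt, data.frame(label = 99, voi_name = "missing"))
  expect_false("missing" %in% extract_voi_means(img, labs, lt2)$voi_name)
  expect_error(extract_voi_means(img, labs[, , 1:2, drop = FALSE], lt),
               "shapes")
})

test_that("NIfTI volumes are accepted as file inputs", {
  skip_if_not_installed("RNifti")
  img <- array(runif(24), dim = c(2, 3, 4))
  labs <- array(sample(1:2, 24, replace = TRUE), dim = c(2, 3, 4))
  fi <- withr::local_tempfile(fileext = ".nii.gz")
  fl <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, fi)
  RNifti::writeNifti(labs, fl)
  lt <- data.frame(label = 1:2, voi_name = c("A", "B"))
  from_file <- extract_voi_means(fi, fl, lt)
  in_memory <- extract_voi_means(img, labs, lt)
  expect_equal(from_file$volume, in_memory$volume)
  expect_equal(from_file$mean_uptake, in_memory$mean_uptake,
               tolerance = 1e-6)  # NIfTI stores float32
})
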