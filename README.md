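# capforge

Perfusable microvascular scaffolds for tissue models are now printable at
capillary scale by two-photon lithography (TPL), but designing them is the
bottleneck: the membrane of a single capillary carries thousands of pores
whose size and spacing must follow the tube along an arbitrary 3D path,
the soft structure must be propped up by supports that neither block
perfusion nor print as unsupported overhangs, and every print must be
checked quantitatively against its design. `capforge` is an R toolkit for
that workflow: parametric porous-tube generation along arbitrary
centerlines, three support systems, chip assembly with STL export, and
the matching print-QC computations (design-vs-print registration maps,
bead-tracking velocimetry, live/dead viability counting).

It is aimed at microfabrication and organ-on-chip researchers who want a
scriptable, reproducible design pipeline instead of a CAD session.

## The design model

A capillary is a cylinder of lumen diameter `l_d` swept along a
centerline of arc length `P_l` with rotation-minimizing frames. The pore
layout comes from a parametric subdivision of that surface: for pore
diameter `p_d` and edge-to-edge pore spacing `p_s`,

    u = floor( P_l / (p_d + p_s) )        axial subdivisions
    v = floor( pi * l_d / (p_d + p_s) )   circumferential subdivisions
    s_l = P_l / u                         axial cell side
    s_r = pi * l_d / v                    circumferential cell side

Each of the `u * v` cells becomes a picture frame: a rectangular opening
inset by `p_s / 2` on every side, so openings are `p_d` across when the
cell pitch divides evenly. Pores facing sideways print closed because the
TPL writing voxel is elongated vertically, so side-facing openings are
stretched circumferentially by 1.5x. The shell is then thickened outward
to the membrane wall thickness (the lumen stays at `l_d`) and optionally
smoothed by Catmull-Clark subdivision.

Supports come in three flavours: polygonal rings (planar paths; anchors
can be placed at predicted field-of-view stitching seams), a
truncated-octahedron lattice with struts culled around the capillary
(full 3D paths), and cone supports with taper >= 15 degrees and the
capillary subtracted (soft materials).

## A worked example

```r
library(capforge)

spec <- capillary_spec(lumen_diameter = 40, pore_diameter = 5,
                       pore_spacing = 8, membrane_thickness = 10)
path <- hilbert_path(order = 2, dims = 2, step = 150, layers = 2,
                     layer_gap = 120, degree = 3,
                     corner_fillet_radius = 20)
grid <- subdivision_grid(path$path_length, spec)
grid
#> <subdivision_grid> u=341 v=9 s_l=13.0221 s_r=13.9626 (3069 cells)

membrane <- sweep_shell(path, grid, spec) |>
  cut_pores(grid, spec) |>
  elongate_side_pores(spec) |>
  thicken(spec$membrane_thickness)
membrane
#> <surface_mesh> 55296 vertices, 122868 faces (membrane)
euler_characteristic(membrane)   # -2 * 3069 pores
#> [1] -6138

pore_size_profile(membrane)
#> # A tibble: 3,069 x 8
#>   pore_id     s theta axial_um circ_um diameter_um elongation normal_z
#>     <int> <dbl> <dbl>    <dbl>   <dbl>       <dbl>      <dbl>    <dbl>
#> 1       1  6.51 0.349     4.96    8.87        4.96        1.5     0.342
#> # i 3,068 more rows
```

The grid has `u = 341` axial and `v = 9` circumferential subdivisions, so
the two-layer design carries 3069 pores; the thickened membrane is
watertight with Euler characteristic `-2 * 3069`, i.e. every pore is a
true through-channel. The same design, including lattice supports, chip
base and STL export, runs as one call from a config file:

```r
run_pipeline(system.file("extdata", "example_chip.yaml",
                         package = "capforge"))
```

or from the shell via `inst/cli/forge.R`:

```sh
Rscript inst/cli/forge.R generate inst/extdata/example_chip.yaml --out out/
Rscript inst/cli/forge.R viability --green g.png --red r.png
```

QC example — recover a flow speed from a synthetic bead movie:

```r
mv  <- synth_bead_movie(1.83, seed = 8)        # mm/s ground truth
tr  <- track_beads(mv$frames, "auto")
estimate_velocity(tr, mv$pixel_size, mv$frame_interval)
#> <flow_estimate> 1.832 +- 0 mm/s over 1 tracks
```

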