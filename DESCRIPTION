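Package: venofsi
Title: Immersed Finite Element Simulation of Venous Valve Fluid-Structure
    Interaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-dimensional fluid-structure interaction simulator for the
    venous valve cycle built on a sharp-interface immersed finite element
    method. A hyperelastic vein wall, sinus pockets and a bileaflet valve are
    meshed with quadrilaterals and immersed in a fixed Eulerian grid on which
    the incompressible Navier-Stokes equations are solved with equal-order
    SUPG/PSPG stabilization. Leaflet-leaflet and leaflet-sinus contact uses a
    12-6 Lennard-Jones adhesive potential. Lesion scenarios (fibrosis and
    atrophy, complete and incomplete) modify leaflet stiffness and thickness.
    Post-processing computes geometric orifice area, transvalvular flow rate,
    venous volumes, wall shear stress on blood and tissue, leaflet rotation
    and a mechanical cost ratio, together with the four phases of the valve
    cycle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
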