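# Absorption coefficient of pure water.
# Units: wavelength_nm [nm]; mua_water [1/cm], natural (base-e) absorption
# coefficient of pure water at room temperature; scaled by volume fraction
# when mixed. Converted to 1/mm at load time (factor 0.1).
# Provenance: approximate reconstruction of the standard pure-water
# absorption compilations (Hale & Querry / Kou et al. style), anchored at
# well-known landmarks (740 nm shoulder, ~975 nm band); NOT a verbatim copy
# of any single published table.
wavelength_nm	mua_water
650	0.00320
660	0.00370
670	0.00430
680	0.00500
690	0.00560
700	0.00620
710	0.00830
720	0.01040
730	0.01680
740	0.02620
750	0.02660
760	0.02570
770	0.02430
780	0.02360
790	0.02220
800	0.02060
810	0.02030
820	0.02650
830	0.02930
840	0.03520
850	0.04330
860	0.04700
870	0.05090
880	0.05460
890	0.06020
900	0.06790
910	0.07740
920	0.10900
930	0.14500
940	0.26900
950	0.38800
960	0.42500
970	0.44800
980	0.43600
990	0.40500
1000	0.36300
1010	0.30000
1020	0.23500
1030	0.19000
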