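# Molar extinction coefficients of human oxyhemoglobin (eps_HbO2) and
# deoxyhemoglobin (eps_Hb) in whole blood, per heme-equivalent molarity.
# Units: wavelength_nm [nm]; eps_HbO2, eps_Hb [1/(cm*M)], decadic (base-10).
# Provenance: approximate reconstruction of the widely used compiled
# tabulations of hemoglobin extinction (Gratzer/Kollias-style compilation).
# Values are smooth interpolations anchored at well-known landmark points
# (690 nm HbO2 minimum, 760 nm Hb band, ~800 nm isosbestic region, NIR
# plateau); they are NOT a verbatim copy of any single published table.
# Converted at load time to 1/(mm*uM) natural-log absorption via
# factor ln(10) * 1e-7.
wavelength_nm	eps_HbO2	eps_Hb
650	368.0	3750.12
660	319.6	3226.56
670	294.0	2795.12
680	277.6	2407.92
690	276.0	2051.96
700	290.0	1794.28
710	314.0	1561.05
720	348.0	1361.88
730	390.0	1102.20
740	446.0	1115.88
750	518.0	1405.24
760	586.0	1548.52
770	650.0	1311.88
780	710.0	1112.00
790	766.0	920.00
800	816.0	761.72
810	864.0	717.08
820	916.0	693.76
830	974.0	693.04
840	1022.0	692.36
850	1058.0	691.32
860	1092.0	694.32
870	1124.0	702.00
880	1154.0	714.00
890	1178.0	732.00
900	1198.2	761.84
910	1212.0	775.00
920	1222.0	788.00
930	1226.0	800.00
940	1226.0	811.00
950	1222.0	822.00
960	1214.0	832.00
970	1200.0	842.00
980	1180.0	852.00
990	1146.0	861.00
1000	1096.0	870.00
1010	1020.0	878.00
1020	930.0	885.00
1030	850.0	891.00
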