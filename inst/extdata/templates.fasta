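>A1_template synthetic template
GMQNVLTQGQQDGQMGGKTLRSTNNIIVKNPDTDYMGLPPDQSVTDSLGAGQTIVQKGVQ
IDGVALQDTMSTIDPDNKMTDMMDNVGVDPNLIHRCNCACVVTMKVLNLCKKNIPLKMGM
VNKDLVQCTMNIMSRNVGNSNDRGLAPDRIQKVLKQIMNDLKQKKVDSPKKVDDLCVGKC
ALPIRPKMMTRASKADRMNVRAKLSLSTMDKTKKDVVDRSVGRTQLRGKKQGICVTTPTL
CPSNVPLKTRPCGAICDGIGLMIKSIDNSPVTDKQHMESYQKTVQTNMPISPDGMPLMKG
PVGLTMVNARARSRQIPVDLAGVSHHLGMPCMQSRSVQKCSRDPSSRGGLTILKIMPPCA
SGMKDRCGKQKNNRNMRLQPQCVLTQIRTDKRNTDLRTQTTCSSCRKRSGHTHSCNRLSC
ACRTTIITKVPIRRAQIGCQSVPATKTINQLIKVKKSNGMMAKKGLITGQDISQRGAKVD
RLAMGNSPNSCCCADSSMVG
>A2_template synthetic template
KSQNPCTKGVQDGMRGGVMIRSPNPKTVLRGDTDYMGLMPRQQPTTQGVPALCNLKLGLQ
LMDVTLQDLVSPICKDNNMTCRKTGVAVSPNLIHRCNCRIRDCSISLKTCKKNIPLKMGM
VNKDLVQCTMNIMSRNVKPCADTPVRITPVTTNNSGILRIANIIIVPKPCKDDLDARTGC
GLQVRLPPGTRASKADRMNVRAKLSLSTMDKTKKDVVDRSVGRTQLCDMTTGKGPTNVTC
MPIMDPDGKRCIIAQCDPCQVPMCDNDDNRARDKQHMYSYQKTTQTLMPISPDGAVLMKG
PVGLTMVNARARSRQIPVDLAGVSHHLGMPSIAACSQLISTANSSGRGGLTILKIMPMMP
ACGMIRASPDLMKPRGGLCRVGIRAVTICPAVMADRPRVGNVCAANKRSGHTHSCNLVKQ
DRVCTIKMVDDDSVASILADSVRICMCCDALPICKKNALMMPPMPCITCKCIRQGGADVD
TPDKATPTSIQPIRLKSRVS
>B_template synthetic template
SVQNNSRKKCPVGQRMIICPCSPNNIRLMNKDTDAMGLMDPQSMTTVGVAVPSDVNKLLK
AMVVALTGTMSTDNTKTCMTDMTLCVAVAPNLIHRCNCPCDMCLINLCPCKKAIPLKMGM
VNKALVQCTMAIMARNVCDACVNSGTPTIVQKGMGQIGNKRKTRPVPAMMTDDDKDCTAC
DKIAVIAQGTRAAKADRMAVRAKLSLSTMDKTKKDVVDRSVGRTQLVNAVQGDGKTCQTL
CPMNMPVKTRSCIVICDRITTNDPQANVKRQADKQHMASYQKTVKGNMPIYPDGQNLMKG
PVGLTMVNARARSRQIPVDLAGVSHHLGMPCCCQKDRQRSSRLPRLRGGLSILTIMPPSS
GDGMIADRKDAINSNGTLCCVAIPPRSMCLRVTADACDVITRTPNPKRSGHTHSCNRLAC
APRSVICSCKVDPISQILKSSVRRCKCCDILLTIKAKILSSDLVRCTTTGNIRSGGCPVD
QPICMGKCDAPLCAKDSMVS
>C_template synthetic template
AGQNLSKGGMQSQNRIGMGIRSRSNRCSNPTDTDAMGLMDNCSQTKVKTRCTKCVQPQLS
IMGCACNDKASAPATDCGDMDMTTDRGSTPNLIHRCNCLAPDCLDVVLPCKKAIPLKMGM
VNKALVQCTMAIMARNVRPKCGTPVAGTIGQDNQKLDGPDDQRRPVSPPAQKDLKMVMDP
GLPVMITCGTRAAKADRMAVRAKLSLSTMDKTKKDVVDRSVGRTQKCDMSPVQGVVCPTK
CSMPMTPKRVPCRVNSDDIKPQQCKNDCDMILDKQHMASAQKTNQTNMPIYPDGKNLMKG
PVGLTMVNAYARSRQIPVDLAGVSHHLGMPCACSASVLISIRISLRRGGLSILAIMPPAS
CDGMIRQGKCQINSNGANPGRGTLVRIGCIIQLSPLRCMMMCTCCIKRSGHTHSCNRSKC
AKRVSIDSLTQDPRNQILTNNVLCCKLDSDNVMRNKQARSMPKLINGCQRDDRTMTCKVD
QPIKAKACAVRPCCARQMVN
>NOR_template synthetic template
TGKILKTPGVQDGQVGGGDDVSCNQNRLRNLDTDAMGLKRTAKANASQNNVSPKVQDNMQ
IPLAALTDTMAMTNRRSDMADATTQTLSDPNLIHRCNCPRPCTLKTRIPCKKAIPLKMGH
AFAELVQCTMAIMARNVGPKTLAINPLTVLQKMKGMPANDNNTRPVMIPCKDCCVVMTGC
MVMAVKKSGTRAAKADRMAHHAFWSLSTMDKTKKDVVDRSVERTQLCQISQGQLPQCPVL
CGGMGSQKTRVCIAIDNGKGPCDGNDDPDVIMDKQHMASAQKTVNTNMPIAPDGACLMKG
PVGLTMVNARARSRQIPVDLAGVSHHLGMACCCSKKTQAVRRNTSKRGGLAILAIMPPPS
AAGMVRASGDKIQSNGQLCRQGIPARCCCPSDSRTLRVVIGCGGCNPRSGHTHSCNRVKP
SNRCTIASCACDQVAMILDVSVVILKNKSALVMGCKCAPRMPKQCTLTCDDINQGPCRVD
QPIKIQKKASKVRMDDQMAS
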